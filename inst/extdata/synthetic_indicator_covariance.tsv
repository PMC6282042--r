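QG	FOR	MARB	JC	TD	CT
QG	0.5128493	0.2067979	0.45696723	0.09590807	0.13786911	0.12757978
FOR	0.2067979	0.22822003	0.28331715	0.06056719	0.08623822	0.08029168
MARB	0.45696723	0.28331715	0.88111535	0.13366514	0.189822	0.17395248
JC	0.09590807	0.06056719	0.13366514	0.51705036	0.42252928	0.38391704
TD	0.13786911	0.08623822	0.189822	0.42252928	0.79524305	0.5586388
CT	0.12757978	0.08029168	0.17395248	0.38391704	0.5586388	0.79065965
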