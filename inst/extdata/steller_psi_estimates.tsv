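group	parameter	estimate	lower	upper
SEAK_F	a01	0.616	0.538	0.690
SEAK_M	a01	0.536	0.441	0.627
SEAK_F	a2	0.905	0.764	0.966
SEAK_M	a2	0.905	0.764	0.966
SEAK_F	a3p	1.000	1.000	1.000
SEAK_M	a3p	1.000	1.000	1.000
Ugamak	a0	0.836	0.778	0.881
PWS	a0	0.601	0.246	0.874
Marmot	a0	0.676	0.598	0.744
Sugarloaf	a0	0.681	0.593	0.757
Ugamak	a1	0.512	0.287	0.732
PWS	a1	0.591	0.176	0.907
Marmot	a1	0.698	0.492	0.846
Sugarloaf	a1	0.186	0.041	0.551
GOA	a01summer	0.118	0.046	0.269
GOA	a2p	0.720	0.493	0.872
SEAK	delta	0.226	0.192	0.265
GOA	delta	0.253	0.226	0.283
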