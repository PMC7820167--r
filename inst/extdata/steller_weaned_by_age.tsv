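group	age	estimate	lower	upper
Ugamak	1	0.855	0.807	0.898
Ugamak	2	0.938	0.909	0.966
Ugamak	3	0.983	0.966	0.993
Ugamak	4	0.995	0.984	0.999
Marmot	1	0.714	0.651	0.779
Marmot	2	0.924	0.866	0.965
Marmot	3	0.979	0.952	0.993
Marmot	4	0.994	0.978	0.999
Sugarloaf	1	0.718	0.645	0.791
Sugarloaf	2	0.798	0.725	0.897
Sugarloaf	3	0.943	0.889	0.980
Sugarloaf	4	0.984	0.946	0.997
PWS	1	0.648	0.341	0.890
PWS	2	0.873	0.722	0.970
PWS	3	0.964	0.912	0.993
PWS	4	0.990	0.963	0.999
SEAK_F	1	0.616	0.538	0.670
SEAK_F	2	0.853	0.786	0.903
SEAK_F	3	0.986	0.963	0.995
SEAK_F	4	1.000	0.969	1.000
SEAK_M	1	0.536	0.441	0.627
SEAK_M	2	0.784	0.688	0.861
SEAK_M	3	0.980	0.947	0.993
SEAK_M	4	1.000	0.955	1.000
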