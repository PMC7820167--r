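model	formula	npar	aic	delta_aic	weight
1	nr * sex + population * day	19	464.1	0.0	0.97
2	nr * sex + day	18	471.2	7.1	0.03
4	nr + sex + population * day	12	488.8	24.6	0.00
5	nr + sex + day	11	496.9	32.8	0.00
3	nr * sex	17	546.5	82.4	0.00
6	nr + sex	10	568.4	104.3	0.00
7	sex + population * day	5	811.3	347.2	0.00
9	sex	3	1465.3	1001.2	0.00
8	sex + day	4	1466.1	1002.0	0.00
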