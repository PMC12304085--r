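# vital-rates configuration
max_age: 15
maturity_age: 4
sex_ratio: 0.5
label: reconstructed
age	survival	fertility
0	1.00000000000000000	0
1	0.50545974195981191	0
2	0.59163120024746374	0
3	0.66893837730732963	0
4	0.73062024447389129	1
5	0.77084637967887415	2
6	0.78562359491856926	3
7	0.77344911250243198	4
8	0.73556239558719672	5
9	0.67573721498203476	6
10	0.59966223969073607	7
11	0.51405088755175243	8
12	0.42567296658286896	9
13	0.34049957392032554	10
14	0.26310410338537499	11
15	0.00000000000000000	12
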