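id,kind,algorithm,D_min,D_max,k,A,B,k1,k2,W,L,dot_edge,box_width,seed
1,linear,ordered,2e-04,0.4444,,,,,,400,400,0.2,1,101
2,linear,ordered,0.001,0.4444,,,,,,400,400,0.2,1,102
3,linear,ordered,0.002,0.4,,,,,,400,400,0.2,1,103
4,linear,ordered,0.005,0.35,,,,,,400,400,0.2,1,104
5,linear,ordered,0.01,0.3,,,,,,400,400,0.2,1,105
6,linear,ordered,0.01,0.2,,,,,,400,400,0.2,1,106
7,linear,ordered,0.02,0.3,,,,,,400,400,0.2,1,107
8,linear,ordered,0.02,0.2,,,,,,400,400,0.2,1,108
9,linear,ordered,0.05,0.3,,,,,,400,400,0.2,1,109
10,linear,ordered,0.1,0.3,,,,,,400,400,0.2,1,110
11,exponential,ordered,2e-04,0.4444,3,,,,,400,400,0.2,1,111
12,exponential,ordered,0.001,0.4444,3,,,,,400,400,0.2,1,112
13,exponential,ordered,0.002,0.4,3,,,,,400,400,0.2,1,113
14,exponential,ordered,0.005,0.35,3,,,,,400,400,0.2,1,114
15,exponential,ordered,0.01,0.3,3,,,,,400,400,0.2,1,115
16,exponential,ordered,0.01,0.2,3,,,,,400,400,0.2,1,116
17,exponential,ordered,0.02,0.3,3,,,,,400,400,0.2,1,117
18,exponential,ordered,0.02,0.2,3,,,,,400,400,0.2,1,118
19,exponential,ordered,0.05,0.3,3,,,,,400,400,0.2,1,119
20,exponential,ordered,0.1,0.3,3,,,,,400,400,0.2,1,120
21,sinusoid_flat,random,0.1,0.1,,0.02,4,,0,400,400,0.2,1,121
22,sinusoid_flat,random,0.12,0.12,,0.05,4,,0,400,400,0.2,1,122
23,sinusoid_flat,random,0.14,0.14,,0.08,8,,0,400,400,0.2,1,123
24,sinusoid_flat,random,0.16,0.16,,0.1,8,,0,400,400,0.2,1,124
25,sinusoid_flat,random,0.18,0.18,,0.06,12,,0,400,400,0.2,1,125
26,sinusoid_flat,random,0.2,0.2,,0.02,12,,0,400,400,0.2,1,126
27,sinusoid_flat,random,0.22,0.22,,0.05,16,,0,400,400,0.2,1,127
28,sinusoid_flat,random,0.24,0.24,,0.08,16,,0,400,400,0.2,1,128
29,sinusoid_flat,random,0.26,0.26,,0.1,22,,0,400,400,0.2,1,129
30,sinusoid_flat,random,0.28,0.28,,0.06,22,,0,400,400,0.2,1,130
31,sinusoid_flat,random,0.12,0.12,,0.04,6,,,400,400,0.2,1,131
32,sinusoid_flat,random,0.16,0.16,,0.06,10,,,400,400,0.2,1,132
33,sinusoid_flat,random,0.2,0.2,,0.08,14,,,400,400,0.2,1,133
34,sinusoid_flat,random,0.24,0.24,,0.1,18,,,400,400,0.2,1,134
35,sinusoid_linear_trend,random,0.01,0.3,,0.05,10,,0,400,400,0.2,1,135
36,sinusoid_linear_trend,random,0.02,0.4,,0.08,15,,0,400,400,0.2,1,136
37,sinusoid_exponential_trend,random,0.01,0.3,,0.1,20,3,3,400,400,0.2,1,137
38,sinusoid_exponential_trend,random,0.01,0.3,,0.05,10,3,3,400,400,0.2,1,138
39,sinusoid_exponential_trend,random,0.02,0.4,,0.08,15,3,3,400,400,0.2,1,139
40,sinusoid_exponential_trend,random,0.005,0.35,,0.06,12,3,3,400,400,0.2,1,140
41,sinusoid_linear_trend,random,0.02,0.26,,0.02,5,,,400,400,0.2,1,141
42,sinusoid_linear_trend,random,0.03,0.27,,0.04,5,,,400,400,0.2,1,142
43,sinusoid_linear_trend,random,0.01,0.28,,0.06,5,,,400,400,0.2,1,143
44,sinusoid_linear_trend,random,0.02,0.29,,0.08,5,,,400,400,0.2,1,144
45,sinusoid_linear_trend,random,0.03,0.25,,0.02,8,,,400,400,0.2,1,145
46,sinusoid_linear_trend,random,0.01,0.26,,0.04,8,,,400,400,0.2,1,146
47,sinusoid_linear_trend,random,0.02,0.27,,0.06,8,,,400,400,0.2,1,147
48,sinusoid_linear_trend,random,0.03,0.28,,0.08,8,,,400,400,0.2,1,148
49,sinusoid_linear_trend,random,0.01,0.29,,0.02,12,,,400,400,0.2,1,149
50,sinusoid_linear_trend,random,0.02,0.25,,0.04,12,,,400,400,0.2,1,150
51,sinusoid_linear_trend,random,0.03,0.26,,0.06,12,,,400,400,0.2,1,151
52,sinusoid_linear_trend,random,0.01,0.27,,0.08,12,,,400,400,0.2,1,152
53,sinusoid_linear_trend,random,0.02,0.28,,0.02,16,,,400,400,0.2,1,153
54,sinusoid_linear_trend,random,0.03,0.29,,0.04,16,,,400,400,0.2,1,154
55,sinusoid_linear_trend,random,0.01,0.25,,0.06,16,,,400,400,0.2,1,155
56,sinusoid_linear_trend,random,0.02,0.26,,0.08,16,,,400,400,0.2,1,156
57,sinusoid_linear_trend,random,0.03,0.27,,0.02,20,,,400,400,0.2,1,157
58,sinusoid_linear_trend,random,0.01,0.28,,0.04,20,,,400,400,0.2,1,158
59,sinusoid_linear_trend,random,0.02,0.29,,0.06,20,,,400,400,0.2,1,159
60,sinusoid_linear_trend,random,0.03,0.25,,0.08,20,,,400,400,0.2,1,160
61,sinusoid_exponential_trend,random,0.02,0.26,,0.02,5,3,,400,400,0.2,1,161
62,sinusoid_exponential_trend,random,0.03,0.27,,0.04,5,3,,400,400,0.2,1,162
63,sinusoid_exponential_trend,random,0.01,0.28,,0.06,5,3,,400,400,0.2,1,163
64,sinusoid_exponential_trend,random,0.02,0.29,,0.08,5,3,,400,400,0.2,1,164
65,sinusoid_exponential_trend,random,0.03,0.25,,0.02,8,3,,400,400,0.2,1,165
66,sinusoid_exponential_trend,random,0.01,0.26,,0.04,8,3,,400,400,0.2,1,166
67,sinusoid_exponential_trend,random,0.02,0.27,,0.06,8,3,,400,400,0.2,1,167
68,sinusoid_exponential_trend,random,0.03,0.28,,0.08,8,3,,400,400,0.2,1,168
69,sinusoid_exponential_trend,random,0.01,0.29,,0.02,12,3,,400,400,0.2,1,169
70,sinusoid_exponential_trend,random,0.02,0.25,,0.04,12,3,,400,400,0.2,1,170
71,sinusoid_exponential_trend,random,0.03,0.26,,0.06,12,3,,400,400,0.2,1,171
72,sinusoid_exponential_trend,random,0.01,0.27,,0.08,12,3,,400,400,0.2,1,172
73,sinusoid_exponential_trend,random,0.02,0.28,,0.02,16,3,,400,400,0.2,1,173
74,sinusoid_exponential_trend,random,0.03,0.29,,0.04,16,3,,400,400,0.2,1,174
75,sinusoid_exponential_trend,random,0.01,0.25,,0.06,16,3,,400,400,0.2,1,175
76,sinusoid_exponential_trend,random,0.02,0.26,,0.08,16,3,,400,400,0.2,1,176
77,sinusoid_exponential_trend,random,0.03,0.27,,0.02,20,3,,400,400,0.2,1,177
78,sinusoid_exponential_trend,random,0.01,0.28,,0.04,20,3,,400,400,0.2,1,178
79,sinusoid_exponential_trend,random,0.02,0.29,,0.06,20,3,,400,400,0.2,1,179
80,sinusoid_exponential_trend,random,0.03,0.25,,0.08,20,3,,400,400,0.2,1,180
81,linear,random,2e-04,0.4444,,,,,,400,400,0.2,1,181
82,linear,random,0.001,0.4444,,,,,,400,400,0.2,1,182
83,linear,random,0.002,0.4,,,,,,400,400,0.2,1,183
84,linear,random,0.005,0.35,,,,,,400,400,0.2,1,184
85,linear,random,0.01,0.3,,,,,,400,400,0.2,1,185
86,linear,random,0.01,0.2,,,,,,400,400,0.2,1,186
87,linear,random,0.02,0.3,,,,,,400,400,0.2,1,187
88,linear,random,0.02,0.2,,,,,,400,400,0.2,1,188
89,linear,random,0.05,0.3,,,,,,400,400,0.2,1,189
90,linear,random,0.1,0.3,,,,,,400,400,0.2,1,190
91,exponential,random,2e-04,0.4444,3,,,,,400,400,0.2,1,191
92,exponential,random,0.001,0.4444,3,,,,,400,400,0.2,1,192
93,exponential,random,0.002,0.4,3,,,,,400,400,0.2,1,193
94,exponential,random,0.005,0.35,3,,,,,400,400,0.2,1,194
95,exponential,random,0.01,0.3,3,,,,,400,400,0.2,1,195
96,exponential,random,0.01,0.2,3,,,,,400,400,0.2,1,196
97,exponential,random,0.02,0.3,3,,,,,400,400,0.2,1,197
98,exponential,random,0.02,0.2,3,,,,,400,400,0.2,1,198
99,exponential,random,0.05,0.3,3,,,,,400,400,0.2,1,199
100,exponential,random,0.1,0.3,3,,,,,400,400,0.2,1,200
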