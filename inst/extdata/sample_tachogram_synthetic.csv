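t_s,rr_ms,gap
1.0234375,1023.4375,0
2.03125,1007.8125,0
3.046875,1015.625,0
4.03125,984.375,0
5.0078125,976.5625,0
6.0078125,1000,0
7.1015625,1093.75,0
8.140625,1039.0625,0
9.2890625,1148.4375,0
10.4375,1148.4375,0
11.6015625,1164.0625,0
12.796875,1195.3125,0
13.8828125,1085.9375,0
14.9375,1054.6875,0
15.9296875,992.1875,0
16.9375,1007.8125,0
17.96875,1031.25,0
18.8671875,898.4375,0
19.6328125,765.625,0
20.484375,851.5625,0
21.34375,859.375,0
22.1484375,804.6875,0
22.9765625,828.125,0
23.8515625,875,0
24.8125,960.9375,0
25.7734375,960.9375,0
26.75,976.5625,0
27.609375,859.375,0
28.5,890.625,0
29.3828125,882.8125,0
30.3515625,968.75,0
31.3515625,1000,0
32.3515625,1000,0
33.296875,945.3125,0
34.296875,1000,0
35.1875,890.625,0
36.0078125,820.3125,0
36.796875,789.0625,0
37.515625,718.75,0
38.3203125,804.6875,0
39.1796875,859.375,0
40.015625,835.9375,0
40.8984375,882.8125,0
41.78125,882.8125,0
42.6171875,835.9375,0
43.4765625,859.375,0
44.265625,789.0625,0
45.15625,890.625,0
46.0703125,914.0625,0
47.046875,976.5625,0
48.015625,968.75,0
48.9296875,914.0625,0
49.984375,1054.6875,0
51.0703125,1085.9375,0
52.09375,1023.4375,0
53.09375,1000,0
54.140625,1046.875,0
55.171875,1031.25,0
55.9921875,820.3125,0
56.84375,851.5625,0
57.7265625,882.8125,0
58.6796875,953.125,0
59.65625,976.5625,0
60.671875,1015.625,0
61.65625,984.375,0
62.7265625,1070.3125,0
63.75,1023.4375,0
64.7734375,1023.4375,0
65.8671875,1093.75,0
67,1132.8125,0
68.015625,1015.625,0
69.015625,1000,0
70.0859375,1070.3125,0
71.09375,1007.8125,0
72.0234375,929.6875,0
72.953125,929.6875,0
73.953125,1000,0
74.9765625,1023.4375,0
75.90625,929.6875,0
76.7578125,851.5625,0
77.75,992.1875,0
78.7890625,1039.0625,0
79.8046875,1015.625,0
80.7734375,968.75,0
81.6953125,921.875,0
82.671875,976.5625,0
83.6015625,929.6875,0
84.484375,882.8125,0
85.4375,953.125,0
86.46875,1031.25,0
87.5625,1093.75,0
88.578125,1015.625,0
89.6484375,1070.3125,0
90.8125,1164.0625,0
91.8359375,1023.4375,0
92.7578125,921.875,0
93.6328125,875,0
94.4609375,828.125,0
95.3046875,843.75,0
96.171875,867.1875,0
97.125,953.125,0
98.1875,1062.5,0
99.1953125,1007.8125,0
100.2578125,1062.5,0
101.2578125,1000,0
102.2890625,1031.25,0
103.265625,976.5625,0
104.1796875,914.0625,0
105.09375,914.0625,0
106.0625,968.75,0
107.0390625,976.5625,0
108,960.9375,0
108.9296875,929.6875,0
109.875,945.3125,0
110.7578125,882.8125,0
111.6171875,859.375,0
112.421875,804.6875,0
113.3984375,976.5625,0
114.3203125,921.875,0
115.25,929.6875,0
116.0625,812.5,0
116.8125,750,0
117.640625,828.125,0
118.484375,843.75,0
119.3515625,867.1875,0
120.1875,835.9375,0
121,812.5,0
121.75,750,0
122.4921875,742.1875,0
123.2734375,781.25,0
124.078125,804.6875,0
124.859375,781.25,0
125.6953125,835.9375,0
126.6484375,953.125,0
127.671875,1023.4375,0
128.6015625,929.6875,0
129.5546875,953.125,0
130.6171875,1062.5,0
131.609375,992.1875,0
132.546875,937.5,0
133.484375,937.5,0
134.3984375,914.0625,0
135.28125,882.8125,0
136.140625,859.375,0
136.9921875,851.5625,0
137.9765625,984.375,0
138.953125,976.5625,0
139.8828125,929.6875,0
140.8359375,953.125,0
141.75,914.0625,0
142.6875,937.5,0
143.515625,828.125,0
144.390625,875,0
145.2578125,867.1875,0
146.1484375,890.625,0
147,851.5625,0
147.8515625,851.5625,0
148.671875,820.3125,0
149.515625,843.75,0
150.4921875,976.5625,0
151.4453125,953.125,0
152.296875,851.5625,0
153.15625,859.375,0
154.0390625,882.8125,0
154.96875,929.6875,0
155.9453125,976.5625,0
156.8515625,906.25,0
157.8359375,984.375,0
158.8515625,1015.625,0
159.8828125,1031.25,0
160.8671875,984.375,0
161.921875,1054.6875,0
162.8671875,945.3125,0
163.859375,992.1875,0
164.859375,1000,0
165.8671875,1007.8125,0
166.8125,945.3125,0
167.78125,968.75,0
168.7578125,976.5625,0
169.7734375,1015.625,0
170.8125,1039.0625,0
171.7734375,960.9375,0
172.7109375,937.5,0
173.671875,960.9375,0
174.640625,968.75,0
175.5078125,867.1875,0
176.3984375,890.625,0
177.3515625,953.125,0
178.3046875,953.125,0
179.1875,882.8125,0
180.0703125,882.8125,0
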