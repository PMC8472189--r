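"number","name","ring_a","ring_b","n_cl"
0,"biphenyl","","",0
1,"2","","2",1
2,"3","","3",1
3,"4","","4",1
4,"2,2'","2","2",2
5,"2,3","","23",2
6,"2,3'","2","3",2
7,"2,4","","24",2
8,"2,4'","2","4",2
9,"2,5","","25",2
10,"2,6","","26",2
11,"3,3'","3","3",2
12,"3,4","","34",2
13,"3,4'","3","4",2
14,"3,5","","35",2
15,"4,4'","4","4",2
16,"2,2',3","2","23",3
17,"2,2',4","2","24",3
18,"2,2',5","2","25",3
19,"2,2',6","2","26",3
20,"2,3,3'","23","3",3
21,"2,3,4","","234",3
22,"2,3,4'","23","4",3
23,"2,3,5","","235",3
24,"2,3,6","","236",3
25,"2,3',4","24","3",3
26,"2,3',5","25","3",3
27,"2,3',6","26","3",3
28,"2,4,4'","24","4",3
29,"2,4,5","","245",3
30,"2,4,6","","246",3
31,"2,4',5","25","4",3
32,"2,4',6","26","4",3
33,"2',3,4","2","34",3
34,"2',3,5","2","35",3
35,"3,3',4","3","34",3
36,"3,3',5","3","35",3
37,"3,4,4'","34","4",3
38,"3,4,5","","345",3
39,"3,4',5","35","4",3
40,"2,2',3,3'","23","23",4
41,"2,2',3,4","2","234",4
42,"2,2',3,4'","23","24",4
43,"2,2',3,5","2","235",4
44,"2,2',3,5'","23","25",4
45,"2,2',3,6","2","236",4
46,"2,2',3,6'","23","26",4
47,"2,2',4,4'","24","24",4
48,"2,2',4,5","2","245",4
49,"2,2',4,5'","24","25",4
50,"2,2',4,6","2","246",4
51,"2,2',4,6'","24","26",4
52,"2,2',5,5'","25","25",4
53,"2,2',5,6'","25","26",4
54,"2,2',6,6'","26","26",4
55,"2,3,3',4","234","3",4
56,"2,3,3',4'","23","34",4
57,"2,3,3',5","235","3",4
58,"2,3,3',5'","23","35",4
59,"2,3,3',6","236","3",4
60,"2,3,4,4'","234","4",4
61,"2,3,4,5","","2345",4
62,"2,3,4,6","","2346",4
63,"2,3,4',5","235","4",4
64,"2,3,4',6","236","4",4
65,"2,3,5,6","","2356",4
66,"2,3',4,4'","24","34",4
67,"2,3',4,5","245","3",4
68,"2,3',4,5'","24","35",4
69,"2,3',4,6","246","3",4
70,"2,3',4',5","25","34",4
71,"2,3',4',6","26","34",4
72,"2,3',5,5'","25","35",4
73,"2,3',5',6","26","35",4
74,"2,4,4',5","245","4",4
75,"2,4,4',6","246","4",4
76,"2',3,4,5","2","345",4
77,"3,3',4,4'","34","34",4
78,"3,3',4,5","3","345",4
79,"3,3',4,5'","34","35",4
80,"3,3',5,5'","35","35",4
81,"3,4,4',5","345","4",4
82,"2,2',3,3',4","23","234",5
83,"2,2',3,3',5","23","235",5
84,"2,2',3,3',6","23","236",5
85,"2,2',3,4,4'","234","24",5
86,"2,2',3,4,5","2","2345",5
87,"2,2',3,4,5'","234","25",5
88,"2,2',3,4,6","2","2346",5
89,"2,2',3,4,6'","234","26",5
90,"2,2',3,4',5","235","24",5
91,"2,2',3,4',6","236","24",5
92,"2,2',3,5,5'","235","25",5
93,"2,2',3,5,6","2","2356",5
94,"2,2',3,5,6'","235","26",5
95,"2,2',3,5',6","236","25",5
96,"2,2',3,6,6'","236","26",5
97,"2,2',3',4,5","23","245",5
98,"2,2',3',4,6","23","246",5
99,"2,2',4,4',5","24","245",5
100,"2,2',4,4',6","24","246",5
101,"2,2',4,5,5'","245","25",5
102,"2,2',4,5,6'","245","26",5
103,"2,2',4,5',6","246","25",5
104,"2,2',4,6,6'","246","26",5
105,"2,3,3',4,4'","234","34",5
106,"2,3,3',4,5","2345","3",5
107,"2,3,3',4',5","235","34",5
108,"2,3,3',4,5'","234","35",5
109,"2,3,3',4,6","2346","3",5
110,"2,3,3',4',6","236","34",5
111,"2,3,3',5,5'","235","35",5
112,"2,3,3',5,6","2356","3",5
113,"2,3,3',5',6","236","35",5
114,"2,3,4,4',5","2345","4",5
115,"2,3,4,4',6","2346","4",5
116,"2,3,4,5,6","","23456",5
117,"2,3,4',5,6","2356","4",5
118,"2,3',4,4',5","245","34",5
119,"2,3',4,4',6","246","34",5
120,"2,3',4,5,5'","245","35",5
121,"2,3',4,5',6","246","35",5
122,"2',3,3',4,5","23","345",5
123,"2',3,4,4',5","24","345",5
124,"2',3,4,5,5'","25","345",5
125,"2',3,4,5,6'","26","345",5
126,"3,3',4,4',5","34","345",5
127,"3,3',4,5,5'","345","35",5
128,"2,2',3,3',4,4'","234","234",6
129,"2,2',3,3',4,5","23","2345",6
130,"2,2',3,3',4,5'","234","235",6
131,"2,2',3,3',4,6","23","2346",6
132,"2,2',3,3',4,6'","234","236",6
133,"2,2',3,3',5,5'","235","235",6
134,"2,2',3,3',5,6","23","2356",6
135,"2,2',3,3',5,6'","235","236",6
136,"2,2',3,3',6,6'","236","236",6
137,"2,2',3,4,4',5","2345","24",6
138,"2,2',3,4,4',5'","234","245",6
139,"2,2',3,4,4',6","2346","24",6
140,"2,2',3,4,4',6'","234","246",6
141,"2,2',3,4,5,5'","2345","25",6
142,"2,2',3,4,5,6","2","23456",6
143,"2,2',3,4,5,6'","2345","26",6
144,"2,2',3,4,5',6","2346","25",6
145,"2,2',3,4,6,6'","2346","26",6
146,"2,2',3,4',5,5'","235","245",6
147,"2,2',3,4',5,6","2356","24",6
148,"2,2',3,4',5,6'","235","246",6
149,"2,2',3,4',5',6","236","245",6
150,"2,2',3,4',6,6'","236","246",6
151,"2,2',3,5,5',6","2356","25",6
152,"2,2',3,5,6,6'","2356","26",6
153,"2,2',4,4',5,5'","245","245",6
154,"2,2',4,4',5,6'","245","246",6
155,"2,2',4,4',6,6'","246","246",6
156,"2,3,3',4,4',5","2345","34",6
157,"2,3,3',4,4',5'","234","345",6
158,"2,3,3',4,4',6","2346","34",6
159,"2,3,3',4,5,5'","2345","35",6
160,"2,3,3',4,5,6","23456","3",6
161,"2,3,3',4,5',6","2346","35",6
162,"2,3,3',4',5,5'","235","345",6
163,"2,3,3',4',5,6","2356","34",6
164,"2,3,3',4',5',6","236","345",6
165,"2,3,3',5,5',6","2356","35",6
166,"2,3,4,4',5,6","23456","4",6
167,"2,3',4,4',5,5'","245","345",6
168,"2,3',4,4',5',6","246","345",6
169,"3,3',4,4',5,5'","345","345",6
170,"2,2',3,3',4,4',5","234","2345",7
171,"2,2',3,3',4,4',6","234","2346",7
172,"2,2',3,3',4,5,5'","2345","235",7
173,"2,2',3,3',4,5,6","23","23456",7
174,"2,2',3,3',4,5,6'","2345","236",7
175,"2,2',3,3',4,5',6","2346","235",7
176,"2,2',3,3',4,6,6'","2346","236",7
177,"2,2',3,3',4',5,6","234","2356",7
178,"2,2',3,3',5,5',6","235","2356",7
179,"2,2',3,3',5,6,6'","2356","236",7
180,"2,2',3,4,4',5,5'","2345","245",7
181,"2,2',3,4,4',5,6","23456","24",7
182,"2,2',3,4,4',5,6'","2345","246",7
183,"2,2',3,4,4',5',6","2346","245",7
184,"2,2',3,4,4',6,6'","2346","246",7
185,"2,2',3,4,5,5',6","23456","25",7
186,"2,2',3,4,5,6,6'","23456","26",7
187,"2,2',3,4',5,5',6","2356","245",7
188,"2,2',3,4',5,6,6'","2356","246",7
189,"2,3,3',4,4',5,5'","2345","345",7
190,"2,3,3',4,4',5,6","23456","34",7
191,"2,3,3',4,4',5',6","2346","345",7
192,"2,3,3',4,5,5',6","23456","35",7
193,"2,3,3',4',5,5',6","2356","345",7
194,"2,2',3,3',4,4',5,5'","2345","2345",8
195,"2,2',3,3',4,4',5,6","234","23456",8
196,"2,2',3,3',4,4',5,6'","2345","2346",8
197,"2,2',3,3',4,4',6,6'","2346","2346",8
198,"2,2',3,3',4,5,5',6","23456","235",8
199,"2,2',3,3',4,5,5',6'","2345","2356",8
200,"2,2',3,3',4,5,6,6'","23456","236",8
201,"2,2',3,3',4,5',6,6'","2346","2356",8
202,"2,2',3,3',5,5',6,6'","2356","2356",8
203,"2,2',3,4,4',5,5',6","23456","245",8
204,"2,2',3,4,4',5,6,6'","23456","246",8
205,"2,3,3',4,4',5,5',6","23456","345",8
206,"2,2',3,3',4,4',5,5',6","2345","23456",9
207,"2,2',3,3',4,4',5,6,6'","23456","2346",9
208,"2,2',3,3',4,5,5',6,6'","23456","2356",9
209,"2,2',3,3',4,4',5,5',6,6'","23456","23456",10
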