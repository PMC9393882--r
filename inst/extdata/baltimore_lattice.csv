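row,col,has_monitor,n_monitors,has_health_data,jurisdiction
1,1,FALSE,0,TRUE,
1,2,FALSE,0,TRUE,
1,3,FALSE,0,TRUE,
1,4,FALSE,0,TRUE,
1,5,FALSE,0,TRUE,
1,6,FALSE,0,TRUE,
1,7,FALSE,0,TRUE,
1,8,FALSE,0,TRUE,
1,9,FALSE,0,TRUE,
2,1,FALSE,0,TRUE,
2,2,FALSE,0,TRUE,
2,3,FALSE,0,TRUE,
2,4,FALSE,0,TRUE,
2,5,FALSE,0,TRUE,
2,6,TRUE,1,TRUE,PG
2,7,FALSE,0,TRUE,
2,8,FALSE,0,TRUE,
2,9,FALSE,0,TRUE,
3,1,FALSE,0,TRUE,
3,2,FALSE,0,TRUE,
3,3,FALSE,0,TRUE,
3,4,FALSE,0,TRUE,
3,5,TRUE,1,TRUE,PG
3,6,FALSE,0,TRUE,
3,7,TRUE,1,TRUE,AA
3,8,FALSE,0,TRUE,
3,9,FALSE,0,TRUE,
4,1,FALSE,0,TRUE,
4,2,FALSE,0,TRUE,
4,3,TRUE,1,TRUE,M
4,4,FALSE,0,TRUE,
4,5,TRUE,1,TRUE,PG
4,6,TRUE,1,TRUE,AA
4,7,FALSE,0,TRUE,
4,8,FALSE,0,TRUE,
4,9,FALSE,0,TRUE,
5,1,FALSE,0,TRUE,
5,2,FALSE,0,TRUE,
5,3,FALSE,0,TRUE,
5,4,FALSE,0,TRUE,
5,5,FALSE,0,TRUE,
5,6,TRUE,1,TRUE,AA
5,7,TRUE,1,TRUE,AA
5,8,FALSE,0,TRUE,
5,9,FALSE,0,TRUE,
6,1,FALSE,0,TRUE,
6,2,FALSE,0,TRUE,
6,3,FALSE,0,TRUE,
6,4,FALSE,0,TRUE,
6,5,FALSE,0,TRUE,
6,6,TRUE,3,TRUE,BC
6,7,TRUE,1,TRUE,BC
6,8,FALSE,0,TRUE,
6,9,FALSE,0,TRUE,
7,1,FALSE,0,TRUE,
7,2,FALSE,0,TRUE,
7,3,FALSE,0,TRUE,
7,4,FALSE,0,TRUE,
7,5,TRUE,1,TRUE,BC
7,6,TRUE,1,TRUE,BC
7,7,TRUE,1,TRUE,B
7,8,FALSE,0,TRUE,
7,9,FALSE,0,TRUE,
8,1,FALSE,0,TRUE,
8,2,FALSE,0,TRUE,
8,3,FALSE,0,TRUE,
8,4,FALSE,0,TRUE,
8,5,FALSE,0,TRUE,
8,6,TRUE,1,TRUE,B
8,7,FALSE,0,TRUE,
8,8,TRUE,1,TRUE,H
8,9,FALSE,0,TRUE,
9,1,FALSE,0,TRUE,
9,2,FALSE,0,TRUE,
9,3,FALSE,0,TRUE,
9,4,FALSE,0,TRUE,
9,5,FALSE,0,TRUE,
9,6,FALSE,0,TRUE,
9,7,FALSE,0,TRUE,
9,8,FALSE,0,TRUE,
9,9,FALSE,0,TRUE,
10,1,FALSE,0,TRUE,
10,2,FALSE,0,TRUE,
10,3,FALSE,0,TRUE,
10,4,FALSE,0,TRUE,
10,5,FALSE,0,TRUE,
10,6,FALSE,0,TRUE,
10,7,FALSE,0,TRUE,
10,8,FALSE,0,TRUE,
10,9,FALSE,0,TRUE,
11,1,FALSE,0,TRUE,
11,2,FALSE,0,TRUE,
11,3,FALSE,0,TRUE,
11,4,FALSE,0,TRUE,
11,5,FALSE,0,TRUE,
11,6,FALSE,0,TRUE,
11,7,FALSE,0,TRUE,
11,8,FALSE,0,TRUE,
11,9,FALSE,0,TRUE,
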