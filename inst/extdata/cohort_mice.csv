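id,sex,lifespan,censored,E_asc,E_desc,ATI
1,M,17.8,FALSE,722,3470,45.34
2,M,18.2,FALSE,1164,719,59.53
3,M,22.37,FALSE,1222,1094,37.87
4,M,13.2,FALSE,746,4418,52.03
5,F,21.9,FALSE,388,1867,53.57
6,F,25,TRUE,1595,781,39.86
7,F,12.3,FALSE,711,3748,35.44
8,F,25,TRUE,930,961,38.78
9,F,25,TRUE,644,631,22.8
10,M,25,TRUE,1033,684,28.74
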