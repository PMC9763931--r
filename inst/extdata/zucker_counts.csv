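group,age_weeks,bed,variant,n
OZR,7,peripheral,five_component,16
OZR,10,peripheral,five_component,16
OZR,13,peripheral,five_component,16
OZR,17,peripheral,five_component,28
OZR,20,peripheral,five_component,0
OZR,7,peripheral,three_component,36
OZR,10,peripheral,three_component,30
OZR,13,peripheral,three_component,36
OZR,17,peripheral,three_component,28
OZR,20,peripheral,three_component,6
OZR,7,cerebral,five_component,8
OZR,10,cerebral,five_component,8
OZR,13,cerebral,five_component,8
OZR,17,cerebral,five_component,8
OZR,20,cerebral,five_component,8
OZR,7,cerebral,three_component,20
OZR,10,cerebral,three_component,8
OZR,13,cerebral,three_component,14
OZR,17,cerebral,three_component,12
OZR,20,cerebral,three_component,8
OZR_EXERCISE,7,peripheral,five_component,7
OZR_EXERCISE,10,peripheral,five_component,7
OZR_EXERCISE,13,peripheral,five_component,7
OZR_EXERCISE,17,peripheral,five_component,7
OZR_EXERCISE,7,peripheral,three_component,7
OZR_EXERCISE,10,peripheral,three_component,7
OZR_EXERCISE,13,peripheral,three_component,7
OZR_EXERCISE,17,peripheral,three_component,23
OZR_CAPTOPRIL,7,peripheral,five_component,4
OZR_CAPTOPRIL,10,peripheral,five_component,4
OZR_CAPTOPRIL,13,peripheral,five_component,4
OZR_CAPTOPRIL,17,peripheral,five_component,4
OZR_CAPTOPRIL,7,peripheral,three_component,4
OZR_CAPTOPRIL,10,peripheral,three_component,4
OZR_CAPTOPRIL,13,peripheral,three_component,4
OZR_CAPTOPRIL,17,peripheral,three_component,4
OZR_CAPTOPRIL,7,cerebral,three_component,6
OZR_CAPTOPRIL,13,cerebral,three_component,6
OZR_CAPTOPRIL,17,cerebral,three_component,6
LZR,7,peripheral,five_component,25
LZR,10,peripheral,five_component,23
LZR,13,peripheral,five_component,24
LZR,17,peripheral,five_component,22
LZR,7,peripheral,three_component,37
LZR,10,peripheral,three_component,29
LZR,13,peripheral,three_component,36
LZR,17,peripheral,three_component,42
LZR,20,peripheral,three_component,6
LZR,7,cerebral,five_component,10
LZR,10,cerebral,five_component,10
LZR,13,cerebral,five_component,10
LZR,17,cerebral,five_component,10
LZR,20,cerebral,five_component,11
LZR,7,cerebral,three_component,22
LZR,10,cerebral,three_component,10
LZR,13,cerebral,three_component,16
LZR,17,cerebral,three_component,12
LZR,20,cerebral,three_component,11
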