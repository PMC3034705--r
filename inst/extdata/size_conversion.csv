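eu_size,eu_label,uk,us_male,us_female
36,36,3,,4.5
36.5,36.5,3.5,,5
37,37,4,,5.5
37.5,37.5,4.5,,6
38,38,5,5.5,6.5
38.5,38.5 - 39,5.5,6,7
39,39 - 39.5,6,6.5,7.5
39.5,39 - 39.5,6,6.5,7.5
40,40,6.5,7,8
40.5,40.5,7,7.5,8.5
41,41 - 41.5,7.5,8,9
41.5,41 - 41.5,7.5,8,9
42,42,8,8.5,9.5
42.5,42.5,8.5,9,10
43,43,9,9.5,
43.5,43.5 - 44,9.5,10,
44,44 - 44.5,10,10.5,
44.5,44 - 44.5,10,10.5,
45,45,10.5,11,
46,46,11,11.5,
46.5,46.5,11.5,12,
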