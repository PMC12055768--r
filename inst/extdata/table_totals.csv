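actor,item,session,seconds,percent_printed
marlatt,total_positive,1,216,8.0
marlatt,total_positive,2,287,11.0
marlatt,total_positive,3,454,16.8
marlatt,total_positive,4,194,7.1
marlatt,total_positive,5,282,10.4
marlatt,total_positive,6,480,17.8
marlatt,total_negative,1,28,0.99
marlatt,total_negative,2,24,0.9
marlatt,total_negative,3,222,8.2
marlatt,total_negative,4,40,1.4
marlatt,total_negative,5,101,3.7
marlatt,total_negative,6,285,10.5
kevin,total_positive,1,156,5.8
kevin,total_positive,2,18,0.6
kevin,total_positive,3,73,2.7
kevin,total_positive,4,22,1.2
kevin,total_positive,5,38,1.4
kevin,total_positive,6,77,2.9
kevin,total_negative,1,312,11.5
kevin,total_negative,2,606,23.1
kevin,total_negative,3,1084,40.1
kevin,total_negative,4,214,11.9
kevin,total_negative,5,814,30.1
kevin,total_negative,6,814,30.1
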