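actor,state,session,seconds,percent_printed
marlatt,negative_affect,1,28,1.0
marlatt,negative_affect,2,24,1.0
marlatt,negative_affect,3,217,8.0
marlatt,negative_affect,4,40,1.4
marlatt,negative_affect,5,101,3.7
marlatt,negative_affect,6,274,10.1
marlatt,control,1,0,0
marlatt,control,2,0,0
marlatt,control,3,5,0.1
marlatt,control,4,0,0
marlatt,control,5,0,0
marlatt,control,6,11,0.3
marlatt,neutral,1,2456,90.96
marlatt,neutral,2,2310,88.13
marlatt,neutral,3,2024,74.96
marlatt,neutral,4,2466,91.33
marlatt,neutral,5,2317,85.81
marlatt,neutral,6,1935,71.67
marlatt,facilitate,1,207,7.7
marlatt,facilitate,2,271,10.3
marlatt,facilitate,3,380,14.1
marlatt,facilitate,4,189,7.0
marlatt,facilitate,5,279,10.3
marlatt,facilitate,6,368,13.6
marlatt,positive_affect,1,9,0.3
marlatt,positive_affect,2,16,0.6
marlatt,positive_affect,3,74,2.7
marlatt,positive_affect,4,5,0.2
marlatt,positive_affect,5,3,0.1
marlatt,positive_affect,6,112,0.4
kevin,negative_affect,1,312,11.5
kevin,negative_affect,2,606,23.1
kevin,negative_affect,3,1032,38.2
kevin,negative_affect,4,198,11.0
kevin,negative_affect,5,809,30.0
kevin,negative_affect,6,760,28.1
kevin,control,1,0,NA
kevin,control,2,0,NA
kevin,control,3,52,2.0
kevin,control,4,16,1.1
kevin,control,5,5,0.1
kevin,control,6,54,2.0
kevin,neutral,1,2232,82.7
kevin,neutral,2,1997,76.1
kevin,neutral,3,1543,57.1
kevin,neutral,4,1564,86.8
kevin,neutral,5,1848,68.4
kevin,neutral,6,1809,67.0
kevin,facilitate,1,156,5.8
kevin,facilitate,2,15,0.6
kevin,facilitate,3,23,0.8
kevin,facilitate,4,9,0.5
kevin,facilitate,5,28,1.0
kevin,facilitate,6,37,1.3
kevin,positive_affect,1,0,NA
kevin,positive_affect,2,3,0.1
kevin,positive_affect,3,50,1.9
kevin,positive_affect,4,16,0.7
kevin,positive_affect,5,10,1.0
kevin,positive_affect,6,40,1.3
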