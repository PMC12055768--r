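actor,code,session,seconds,percent_printed
marlatt,Low Domineering,1,0,0
marlatt,Low Domineering,2,0,0
marlatt,Low Domineering,3,5,0.19
marlatt,Low Domineering,4,0,0
marlatt,Low Domineering,5,0,0
marlatt,Low Domineering,6,11,0.41
marlatt,Tension,1,18,0.67
marlatt,Tension,2,24,0.92
marlatt,Tension,3,170,6.3
marlatt,Tension,4,23,0.85
marlatt,Tension,5,96,3.56
marlatt,Tension,6,229,8.48
marlatt,Tense Humor,1,10,0.37
marlatt,Tense Humor,2,0,0
marlatt,Tense Humor,3,47,1.74
marlatt,Tense Humor,4,16,0.59
marlatt,Tense Humor,5,5,0.19
marlatt,Tense Humor,6,45,1.67
marlatt,Sadness,1,0,0
marlatt,Sadness,2,0,0
marlatt,Sadness,3,0,0
marlatt,Sadness,4,1,0.04
marlatt,Sadness,5,0,0
marlatt,Sadness,6,0,0
marlatt,Neutral,1,2456,90.96
marlatt,Neutral,2,2310,88.1
marlatt,Neutral,3,2024,74.96
marlatt,Neutral,4,2466,91.33
marlatt,Neutral,5,2317,85.81
marlatt,Neutral,6,1935,71.67
marlatt,Interest,1,36,1.33
marlatt,Interest,2,64,2.44
marlatt,Interest,3,59,2.19
marlatt,Interest,4,30,1.11
marlatt,Interest,5,16,0.59
marlatt,Interest,6,50,1.85
marlatt,Low Validation,1,158,5.85
marlatt,Low Validation,2,151,9.33
marlatt,Low Validation,3,260,4.37
marlatt,Low Validation,4,129,8.90
marlatt,Low Validation,5,216,8.89
marlatt,Low Validation,6,212,7.85
marlatt,High Validation,1,13,0.48
marlatt,High Validation,2,56,2.14
marlatt,High Validation,3,61,2.26
marlatt,High Validation,4,30,1.11
marlatt,High Validation,5,47,1.74
marlatt,High Validation,6,106,3.93
marlatt,Affection,1,9,0.33
marlatt,Affection,2,3,0.11
marlatt,Affection,3,63,2.33
marlatt,Affection,4,5,0.19
marlatt,Affection,5,0,0
marlatt,Affection,6,103,3.81
marlatt,Humor,1,0,NA
marlatt,Humor,2,13,0.50
marlatt,Humor,3,10,0.37
marlatt,Humor,4,0,0
marlatt,Humor,5,3,0.11
marlatt,Humor,6,9,0.33
marlatt,Surprise/Joy,1,0,0
marlatt,Surprise/Joy,2,0,0
marlatt,Surprise/Joy,3,1,0.04
marlatt,Surprise/Joy,4,0,0
marlatt,Surprise/Joy,5,0,0
marlatt,Surprise/Joy,6,0,0
kevin,Disgust,1,0,NA
kevin,Disgust,2,0,NA
kevin,Disgust,3,1,0.01
kevin,Disgust,4,1,0.01
kevin,Disgust,5,0,NA
kevin,Disgust,6,1,0.01
kevin,Contempt,1,0,NA
kevin,Contempt,2,0,NA
kevin,Contempt,3,0,NA
kevin,Contempt,4,1,0.01
kevin,Contempt,5,0,NA
kevin,Contempt,6,9,0.03
kevin,Low Domineering,1,0,NA
kevin,Low Domineering,2,0,NA
kevin,Low Domineering,3,39,1.44
kevin,Low Domineering,4,13,0.72
kevin,Low Domineering,5,0,NA
kevin,Low Domineering,6,24,1.0
kevin,Criticism,1,0,NA
kevin,Criticism,2,0,NA
kevin,Criticism,3,4,0.10
kevin,Criticism,4,0,NA
kevin,Criticism,5,0,NA
kevin,Criticism,6,0,NA
kevin,Anger,1,0,NA
kevin,Anger,2,207,7.9
kevin,Anger,3,87,3.2
kevin,Anger,4,21,1.2
kevin,Anger,5,178,6.6
kevin,Anger,6,78,2.7
kevin,Tension,1,247,9.14
kevin,Tension,2,178,6.8
kevin,Tension,3,529,19.5
kevin,Tension,4,95,5.3
kevin,Tension,5,165,6.1
kevin,Tension,6,252,9.3
kevin,Tense Humor,1,9,0.33
kevin,Tense Humor,2,9,0.34
kevin,Tense Humor,3,42,1.5
kevin,Tense Humor,4,9,0.5
kevin,Tense Humor,5,9,0.3
kevin,Tense Humor,6,51,1.9
kevin,Defensiveness,1,0,NA
kevin,Defensiveness,2,0,NA
kevin,Defensiveness,3,9,0.03
kevin,Defensiveness,4,3,0.01
kevin,Defensiveness,5,5,0.01
kevin,Defensiveness,6,30,1.1
kevin,Sadness,1,56,2.1
kevin,Sadness,2,212,8.0
kevin,Sadness,3,373,13.8
kevin,Sadness,4,71,4.0
kevin,Sadness,5,457,17.0
kevin,Sadness,6,374,14.0
kevin,Neutral,1,2232,82.7
kevin,Neutral,2,1997,76.1
kevin,Neutral,3,1543,57.1
kevin,Neutral,4,1564,86.8
kevin,Neutral,5,1848,68.4
kevin,Neutral,6,1809,67.0
kevin,Interest,1,33,1.2
kevin,Interest,2,0,NA
kevin,Interest,3,3,0.1
kevin,Interest,4,0,NA
kevin,Interest,5,0,NA
kevin,Interest,6,2,0.1
kevin,Low Validation,1,111,4.1
kevin,Low Validation,2,15,0.1
kevin,Low Validation,3,2,0.1
kevin,Low Validation,4,0,NA
kevin,Low Validation,5,13,0.5
kevin,Low Validation,6,13,0.5
kevin,High Validation,1,12,1.2
kevin,High Validation,2,0,NA
kevin,High Validation,3,18,0.7
kevin,High Validation,4,9,0.5
kevin,High Validation,5,15,0.5
kevin,High Validation,6,22,0.8
kevin,Affection,1,0,NA
kevin,Affection,2,0,NA
kevin,Affection,3,31,1.1
kevin,Affection,4,0,NA
kevin,Affection,5,6,0.2
kevin,Affection,6,26,0.9
kevin,Humor,1,0,NA
kevin,Humor,2,3,0.1
kevin,Humor,3,15,0.5
kevin,Humor,4,13,0.7
kevin,Humor,5,4,0.1
kevin,Humor,6,11,0.4
kevin,Surprise/Joy,1,0,NA
kevin,Surprise/Joy,2,0,NA
kevin,Surprise/Joy,3,4,0.1
kevin,Surprise/Joy,4,0,NA
kevin,Surprise/Joy,5,0,NA
kevin,Surprise/Joy,6,3,0.1
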