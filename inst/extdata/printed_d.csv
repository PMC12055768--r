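actor,scope,item,D,reference,note
marlatt,code,Low Domineering,0.388,normal_fitted,
marlatt,code,Sadness,0.492,normal_fitted,
marlatt,code,Affection,0.360,normal_fitted,exact percentages give 0.3596
marlatt,code,Surprise/Joy,0.492,normal_fitted,
kevin,code,Disgust,0.500,exponential_fitted,
kevin,code,Contempt,0.667,exponential_fitted,
kevin,code,Low Domineering,0.500,exponential_fitted,
kevin,code,Tension,0.430,exponential_fitted,
kevin,code,Neutral,0.543,exponential_fitted,
kevin,code,Interest,0.500,exponential_fitted,
kevin,code,High Validation,0.424,exponential_fitted,
kevin,code,Affection,0.500,exponential_fitted,
kevin,code,Surprise/Joy,0.667,exponential_fitted,
marlatt,meta,control,0.667,exponential_fitted,
marlatt,meta,positive_affect,0.486,exponential_fitted,not reproduced under any tested reference
kevin,meta,facilitate,0.395,normal_fitted,
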