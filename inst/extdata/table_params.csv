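actor,session,a2,r2,unss,nth,pth,kr,sr
marlatt,1,-0.1324441,0.3611994,-0.2073325,-1.6,0.6,-1,1.2
marlatt,2,0.1408405,0.307107,0.20326443,-3.8,-1.3,-2.5,6.1
marlatt,3,-0.2510611,0.2716847,-0.3447149,-5,-3,NA,NA
marlatt,4,-0.1201938,0.07043698,-0.1293014,-1.1,-0.5,NA,NA
marlatt,5,-0.5614022,0.2544554,-0.7530095,-2.7,0,-2.6,3.3
marlatt,6,0.1218353,0.6107724,0.31301814,-6,-1.8,-2.7,3
kevin,1,0.1652314,0.4301383,0.28995,NA,0.2,-2.7,1.9
kevin,2,-0.7105349,0.714605,-2.4896543,NA,-0.2,-9.5,0.5
kevin,3,-0.6360675,0.72216,-2.2893302,-2.6,-1,NA,NA
kevin,4,-0.4974667,0.4330673,-0.8774705,NA,-1,NA,NA
kevin,5,-0.559131,0.7634271,-2.3634617,-1.2,0.2,NA,NA
kevin,6,-1.038966,0.4618898,-1.9307681,-0.6,0.6,NA,NA
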