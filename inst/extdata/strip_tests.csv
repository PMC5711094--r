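test,energy,position_cm,strip_mean,strip_sd,open_mean,open_sd
DR_GS,6X,-5,74.06,0.42,68.38,0.16
DR_GS,6X,-3,74.18,0.37,69.32,0.08
DR_GS,6X,-1,73.95,0.42,69.28,0.07
DR_GS,6X,1,73.96,0.37,69.42,0.09
DR_GS,6X,3,73.81,0.39,69.38,0.08
DR_GS,6X,5,73.87,0.49,69.38,0.1
DR_GS,6X,7,71.73,0.57,67.32,0.25
DR_GS,6X-FFF,-5,38354.5,71.7,39924.8,152.6
DR_GS,6X-FFF,-3,37602.75,86.4,39358.1,113.2
DR_GS,6X-FFF,-1,37124.7,63.9,39047.5,103.1
DR_GS,6X-FFF,1,37209.2,58,38985.4,115
DR_GS,6X-FFF,3,37278.4,90.7,39145.2,97
DR_GS,6X-FFF,5,38009.6,111.7,39614,219.9
DR_GS,6X-FFF,7,38792.8,91.6,40215.6,118
LS_DR,6X,-4.5,37.37,0.37,67.12,0.11
LS_DR,6X,-1.5,37.63,0.96,67.34,0.2
LS_DR,6X,1.5,37.09,0.34,66.78,0.06
LS_DR,6X,4.5,36.15,0.4,65.32,0.16
LS_DR,6X-FFF,-4.5,41931.7,122.7,40158.9,196.1
LS_DR,6X-FFF,-1.5,41521.8,110.4,39626.7,119.6
LS_DR,6X-FFF,1.5,41499.2,88,39533.6,120
LS_DR,6X-FFF,4.5,41884.7,122.3,40153.9,158.6
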