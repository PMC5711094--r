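case,technique,energy,region,rate
Prostate,IMRT,6X,low,99.1
H&N,IMRT,6X,low,99.2
C-shape hard,IMRT,6X,low,99.7
C-shape easy,IMRT,6X,low,99.5
Prostate,IMRT,10X,low,99.6
H&N,IMRT,10X,low,99.9
C-shape hard,IMRT,10X,low,94.2
C-shape easy,IMRT,10X,low,99.1
Prostate,IMRT,15X,low,98.1
H&N,IMRT,15X,low,100
C-shape hard,IMRT,15X,low,96.9
C-shape easy,IMRT,15X,low,97.9
Prostate,IMRT,6X-FFF,low,98.6
H&N,IMRT,6X-FFF,low,99.8
C-shape hard,IMRT,6X-FFF,low,99.5
C-shape easy,IMRT,6X-FFF,low,93.7
Prostate,IMRT,10X-FFF,low,99.1
H&N,IMRT,10X-FFF,low,99.8
C-shape hard,IMRT,10X-FFF,low,95.4
C-shape easy,IMRT,10X-FFF,low,89.3
Prostate,RapidArc,6X,low,99.9
H&N,RapidArc,6X,low,99.8
C-shape hard,RapidArc,6X,low,100
C-shape easy,RapidArc,6X,low,96.6
Prostate,RapidArc,10X,low,98.8
H&N,RapidArc,10X,low,99.4
C-shape hard,RapidArc,10X,low,99.9
C-shape easy,RapidArc,10X,low,98.1
Prostate,RapidArc,15X,low,100
H&N,RapidArc,15X,low,99.8
C-shape hard,RapidArc,15X,low,100
C-shape easy,RapidArc,15X,low,100
Prostate,RapidArc,6X-FFF,low,93.2
H&N,RapidArc,6X-FFF,low,99.9
C-shape hard,RapidArc,6X-FFF,low,99.9
C-shape easy,RapidArc,6X-FFF,low,100
Prostate,RapidArc,10X-FFF,low,99.7
H&N,RapidArc,10X-FFF,low,99.9
C-shape hard,RapidArc,10X-FFF,low,98.5
C-shape easy,RapidArc,10X-FFF,low,99.9
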