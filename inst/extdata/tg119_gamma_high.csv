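case,technique,energy,region,rate
Prostate,IMRT,6X,high,96.7
H&N,IMRT,6X,high,97.8
C-shape hard,IMRT,6X,high,99.9
C-shape easy,IMRT,6X,high,99.4
MultiTarget,IMRT,6X,high,92.9
Prostate,IMRT,10X,high,99.5
H&N,IMRT,10X,high,99.3
C-shape hard,IMRT,10X,high,99.5
C-shape easy,IMRT,10X,high,89.2
MultiTarget,IMRT,10X,high,99.3
Prostate,IMRT,15X,high,99.2
H&N,IMRT,15X,high,99.1
C-shape hard,IMRT,15X,high,88.5
C-shape easy,IMRT,15X,high,98.9
MultiTarget,IMRT,15X,high,99
Prostate,IMRT,6X-FFF,high,99
H&N,IMRT,6X-FFF,high,93.6
C-shape hard,IMRT,6X-FFF,high,96.8
C-shape easy,IMRT,6X-FFF,high,98.1
MultiTarget,IMRT,6X-FFF,high,97.4
Prostate,IMRT,10X-FFF,high,97.8
H&N,IMRT,10X-FFF,high,99.4
C-shape hard,IMRT,10X-FFF,high,93.9
C-shape easy,IMRT,10X-FFF,high,98.5
MultiTarget,IMRT,10X-FFF,high,99.6
Prostate,RapidArc,6X,high,100
H&N,RapidArc,6X,high,98.6
C-shape hard,RapidArc,6X,high,99.9
C-shape easy,RapidArc,6X,high,99.9
MultiTarget,RapidArc,6X,high,100
Prostate,RapidArc,10X,high,96.9
H&N,RapidArc,10X,high,98.3
C-shape hard,RapidArc,10X,high,99.9
C-shape easy,RapidArc,10X,high,98
MultiTarget,RapidArc,10X,high,99.9
Prostate,RapidArc,15X,high,99.9
H&N,RapidArc,15X,high,98.5
C-shape hard,RapidArc,15X,high,99.4
C-shape easy,RapidArc,15X,high,99.9
MultiTarget,RapidArc,15X,high,98.1
Prostate,RapidArc,6X-FFF,high,100
H&N,RapidArc,6X-FFF,high,99.9
C-shape hard,RapidArc,6X-FFF,high,97.5
C-shape easy,RapidArc,6X-FFF,high,99.9
MultiTarget,RapidArc,6X-FFF,high,99.5
Prostate,RapidArc,10X-FFF,high,98
H&N,RapidArc,10X-FFF,high,99.5
C-shape hard,RapidArc,10X-FFF,high,92.6
C-shape easy,RapidArc,10X-FFF,high,95.1
MultiTarget,RapidArc,10X-FFF,high,97.3
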