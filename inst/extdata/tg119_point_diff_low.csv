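case,technique,energy,region,diff_pct
Prostate,IMRT,6X,low,2.5
H&N,IMRT,6X,low,0.1
C-shape hard,IMRT,6X,low,1.9
C-shape easy,IMRT,6X,low,0.7
MultiTarget (Sup),IMRT,6X,low,1.2
MultiTarget (Inf),IMRT,6X,low,1.4
Prostate,IMRT,10X,low,-0.1
H&N,IMRT,10X,low,-1.1
C-shape hard,IMRT,10X,low,1.8
C-shape easy,IMRT,10X,low,-0.4
MultiTarget (Sup),IMRT,10X,low,-0.9
MultiTarget (Inf),IMRT,10X,low,-1
Prostate,IMRT,15X,low,0
H&N,IMRT,15X,low,-1.7
C-shape hard,IMRT,15X,low,1
C-shape easy,IMRT,15X,low,-0.6
MultiTarget (Sup),IMRT,15X,low,-1.3
MultiTarget (Inf),IMRT,15X,low,-1.5
Prostate,IMRT,6X-FFF,low,2.1
H&N,IMRT,6X-FFF,low,1.4
C-shape hard,IMRT,6X-FFF,low,0
C-shape easy,IMRT,6X-FFF,low,0.1
MultiTarget (Sup),IMRT,6X-FFF,low,1.4
MultiTarget (Inf),IMRT,6X-FFF,low,1.3
Prostate,IMRT,10X-FFF,low,-1.6
H&N,IMRT,10X-FFF,low,-1.3
C-shape hard,IMRT,10X-FFF,low,1.3
C-shape easy,IMRT,10X-FFF,low,0.7
MultiTarget (Sup),IMRT,10X-FFF,low,-2.5
MultiTarget (Inf),IMRT,10X-FFF,low,-1.8
Prostate,RapidArc,6X,low,4.7
H&N,RapidArc,6X,low,2
C-shape hard,RapidArc,6X,low,0.7
C-shape easy,RapidArc,6X,low,0.4
MultiTarget (Sup),RapidArc,6X,low,1.1
MultiTarget (Inf),RapidArc,6X,low,0.8
Prostate,RapidArc,10X,low,2
H&N,RapidArc,10X,low,1.2
C-shape hard,RapidArc,10X,low,0.4
C-shape easy,RapidArc,10X,low,0.4
MultiTarget (Sup),RapidArc,10X,low,0.8
MultiTarget (Inf),RapidArc,10X,low,0.3
Prostate,RapidArc,15X,low,1.3
H&N,RapidArc,15X,low,1
C-shape hard,RapidArc,15X,low,-0.4
C-shape easy,RapidArc,15X,low,-0.1
MultiTarget (Sup),RapidArc,15X,low,0.7
MultiTarget (Inf),RapidArc,15X,low,-0.1
Prostate,RapidArc,6X-FFF,low,2.1
H&N,RapidArc,6X-FFF,low,1.7
C-shape hard,RapidArc,6X-FFF,low,-1.6
C-shape easy,RapidArc,6X-FFF,low,0.5
MultiTarget (Sup),RapidArc,6X-FFF,low,0.3
MultiTarget (Inf),RapidArc,6X-FFF,low,0.2
Prostate,RapidArc,10X-FFF,low,0.6
H&N,RapidArc,10X-FFF,low,1.1
C-shape hard,RapidArc,10X-FFF,low,-0.6
C-shape easy,RapidArc,10X-FFF,low,1.1
MultiTarget (Sup),RapidArc,10X-FFF,low,-0.3
MultiTarget (Inf),RapidArc,10X-FFF,low,0.1
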