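case,technique,energy,region,diff_pct
Prostate,IMRT,6X,high,1.5
H&N,IMRT,6X,high,0.5
C-shape hard,IMRT,6X,high,0.1
C-shape easy,IMRT,6X,high,1
MultiTarget,IMRT,6X,high,1.6
Prostate,IMRT,10X,high,0
H&N,IMRT,10X,high,-1.9
C-shape hard,IMRT,10X,high,-0.9
C-shape easy,IMRT,10X,high,-1.3
MultiTarget,IMRT,10X,high,0
Prostate,IMRT,15X,high,0.1
H&N,IMRT,15X,high,-2.2
C-shape hard,IMRT,15X,high,-2.1
C-shape easy,IMRT,15X,high,-2.1
MultiTarget,IMRT,15X,high,0
Prostate,IMRT,6X-FFF,high,1.8
H&N,IMRT,6X-FFF,high,2.1
C-shape hard,IMRT,6X-FFF,high,0.4
C-shape easy,IMRT,6X-FFF,high,1.4
MultiTarget,IMRT,6X-FFF,high,1.9
Prostate,IMRT,10X-FFF,high,-1.6
H&N,IMRT,10X-FFF,high,-3.1
C-shape hard,IMRT,10X-FFF,high,-0.7
C-shape easy,IMRT,10X-FFF,high,0.2
MultiTarget,IMRT,10X-FFF,high,-1.8
Prostate,RapidArc,6X,high,0.8
H&N,RapidArc,6X,high,0.3
C-shape hard,RapidArc,6X,high,3.3
C-shape easy,RapidArc,6X,high,2.9
MultiTarget,RapidArc,6X,high,1.1
Prostate,RapidArc,10X,high,0
H&N,RapidArc,10X,high,-0.3
C-shape hard,RapidArc,10X,high,1.5
C-shape easy,RapidArc,10X,high,1.5
MultiTarget,RapidArc,10X,high,0.4
Prostate,RapidArc,15X,high,-0.2
H&N,RapidArc,15X,high,-0.1
C-shape hard,RapidArc,15X,high,1
C-shape easy,RapidArc,15X,high,0
MultiTarget,RapidArc,15X,high,1.1
Prostate,RapidArc,6X-FFF,high,-0.3
H&N,RapidArc,6X-FFF,high,0.2
C-shape hard,RapidArc,6X-FFF,high,2.3
C-shape easy,RapidArc,6X-FFF,high,1.2
MultiTarget,RapidArc,6X-FFF,high,1
Prostate,RapidArc,10X-FFF,high,-0.9
H&N,RapidArc,10X-FFF,high,0.1
C-shape hard,RapidArc,10X-FFF,high,-1
C-shape easy,RapidArc,10X-FFF,high,3.1
MultiTarget,RapidArc,10X-FFF,high,0.4
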