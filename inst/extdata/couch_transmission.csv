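energy,section,calculated,measured
6X,thick,0.9767,0.9682
10X,thick,0.9733,0.963
15X,thick,0.9829,0.9763
6X-FFF,thick,0.9791,0.9727
10X-FFF,thick,0.9846,0.9784
6X,thin,0.9825,0.9744
10X,thin,0.9794,0.9723
15X,thin,0.9861,0.9829
6X-FFF,thin,0.9835,0.9799
10X-FFF,thin,0.9877,0.9851
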