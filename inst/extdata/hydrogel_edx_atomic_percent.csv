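sample_id,element,atomic_percent
Ba-alg,Ba,2.74
Ba-alg,C,51.16
Ba-alg,O,45.81
Ba-alg,Na,0.14
Ba-alg,Cl,0.05
Ba-alg,Al,0.06
Ba-alg,Si,0.04
Sr-alg,Sr,6.47
Sr-alg,C,43.18
Sr-alg,O,41.73
Sr-alg,Na,0.36
Sr-alg,Cl,8.27
Sr-alg-washed,Sr,2.71
Sr-alg-washed,C,50.04
Sr-alg-washed,O,47.25
Ca-alg,Ca,6.48
Ca-alg,C,43.3
Ca-alg,O,38.51
Ca-alg,Na,0.49
Ca-alg,Cl,11.15
Ca-alg,Al,0.04
Ca-alg,Si,0.03
Zn-alg,Zn,5.02
Zn-alg,C,40.68
Zn-alg,O,51.33
Zn-alg,S,2.87
Zn-alg,Al,0.05
Zn-alg,Si,0.05
Cu-alg,Cu,2.68
Cu-alg,C,32.4
Cu-alg,O,62.23
Cu-alg,S,2.6
Cu-alg,Al,0.05
Cu-alg,Si,0.04
Ni-alg,Ni,6.49
Ni-alg,C,26.07
Ni-alg,O,62.45
Ni-alg,S,4.94
Ni-alg,Al,0.03
Ni-alg,Si,0.02
Mn-alg,Mn,11.8
Mn-alg,C,45.8
Mn-alg,O,24.99
Mn-alg,Na,0.12
Mn-alg,Cl,17.2
Mn-alg,Al,0.05
Mn-alg,Si,0.04
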