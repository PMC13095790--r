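modality,grade,n
photon,0,2
photon,1,9
photon,2,25
photon,3,54
photon,4,4
proton,0,8
proton,1,6
proton,2,11
proton,3,12
proton,4,0
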