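class,sitting,walking,climbing_stairs,ankle_dorsiflexion,ankle_plantarflexion,cycling
sitting,97.3,0.9,0.6,0.5,0.4,0.3
walking,2.2,94.8,2.3,0.1,0.1,0.5
climbing_stairs,0.7,1.7,92.4,1.9,2.6,0.7
ankle_dorsiflexion,1.7,0.9,1.7,91.3,3.2,1.2
ankle_plantarflexion,2.4,1.0,2.2,2.5,90.8,1.1
cycling,0.5,1.8,1.5,1.3,1.6,93.3
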