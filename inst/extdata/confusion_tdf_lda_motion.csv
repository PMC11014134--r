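class,sitting,walking,climbing_stairs,ankle_dorsiflexion,ankle_plantarflexion,cycling
sitting,90.7,2.1,1.9,2.1,1.9,1.3
walking,2.6,89.9,2.5,1.9,1.4,1.7
climbing_stairs,2.5,3.2,85.6,2.8,3.1,2.8
ankle_dorsiflexion,2.9,3.2,2.6,83.7,4.7,2.9
ankle_plantarflexion,3.7,1.8,3.9,3.9,84.9,1.8
cycling,2.2,3.1,1.9,2.2,2.9,87.7
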