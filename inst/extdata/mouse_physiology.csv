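tissue,volume_frac,flow_frac,density
lung,0.0073,NA,1.0
heart,0.0050,0.0660,1.0
kidney,0.0167,0.1625,1.0
liver,0.0549,0.0250,1.0
spleen,0.0035,0.0200,1.0
gut,0.0422,0.1800,1.0
muscle,0.3840,0.1590,1.0
adipose,0.0700,0.0700,1.0
skin,0.1650,0.0580,1.0
bone,0.1073,0.1100,1.0
brain,0.0165,0.0330,1.0
rest_of_body,0.0506,0.1165,1.0
arterial_blood,0.0257,NA,1.0
venous_blood,0.0513,NA,1.0
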