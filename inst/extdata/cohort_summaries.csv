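measure,group,n,mean,sd
age,lvPPA,13,65.9,7.5
age,svPPA,11,63.8,7.4
age,control,34,62.8,7.9
education,lvPPA,13,14.6,2.8
education,svPPA,11,17.2,3.4
education,control,34,15.3,2.5
mmse,lvPPA,13,22.8,3.9
mmse,svPPA,11,22.4,6.5
duration,lvPPA,13,2.7,1.8
duration,svPPA,11,3.9,2.6
animals_z,lvPPA,13,-2.3,0.9
animals_z,svPPA,11,-2.8,0.8
bnt_z,lvPPA,13,-5.6,3.8
bnt_z,svPPA,11,-13.2,3.4
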