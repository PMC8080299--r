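class,code,severity,t2d_code
routine_checkup,68B..,0,FALSE
eczema,M111.,0,FALSE
hypertension,G20..,0,FALSE
hayfever,H170.,0,FALSE
back_pain,N142.,1,FALSE
osteoarthritis,N05..,1,FALSE
depression,E112.,1,FALSE
angina,G33..,1,FALSE
hip_fracture,S30..,2,FALSE
stroke,G66..,2,FALSE
copd_severe,H3122,2,FALSE
severe_arthritis,N040.,2,FALSE
t2d_incident,C10F.,0,TRUE
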