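code	category	medicinal
AFNI	Animal food	0
AVNT	Anti-venom	1
BACL	Blood and circulatory system	1
COSM	Cosmetic	0
CULT	Cultural	0
CIUL	Cultural illnesses	1
DHEN	Dental health	1
DSIG	Digestive system	1
ESND	Endocrine system	1
HFUM	Human food	0
IAIN	Infections and infestations	1
MANE	Metabolism and nutrition	1
MSSU	Muscular-skelettal system	1
NSAE	Nervous system and mental health	1
NSSO	Non-specific symptoms and general illnesses	1
OTHE	Others	1
PCAR	Pregnancy, childbirth and child-bed	1
RSAE	Reproductive system and sexual health	1
RSES	Respitarory system	1
SSEN	Sensory system	1
SASK	Skin and subcutaneous tissue	1
TOXI	Toxic	0
USRI	Urinary system	1
VETE	Veterinary	1
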