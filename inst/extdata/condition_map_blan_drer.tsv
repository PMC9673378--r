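condition_a	condition_b
embryo	embryo
male_gonads	testis
muscle	muscle_tissue
neural_tube	brain
gut	intestine
gills	pharyngeal_gill
hepatic_diverticulum	liver
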