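eGFR decline
eGFR
polyuria-polydipsia
failure to thrive
recurrent urinary tract infections
hypercalciuria
nephrocalcinosis
hypomagnesemia
hyperparathyroidism
high myopia
macular thickness
retinal detachment
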