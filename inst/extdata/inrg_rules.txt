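# Outcome rules over the three common risk factors (INSS stage, MYCN status,
# Age at diagnosis), as printed for the 182-patient training cohort.
if INSS in {1, 3, 4, 4s} and MYCN in {amplified} and Age in {>=1} then Outcome = Poor
if INSS in {4} and Age in {>=1} then Outcome = Poor
if INSS in {1, 2, 4s} and Age in {<1} then Outcome = Good
if INSS in {1, 2, 3, 4s} and MYCN in {normal} then Outcome = Good
if Age in {<1} then Outcome = Good
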