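# The four-rule final classifier over stage, MYCN, age and the dichotomized
# hypoxia signature.
if INSS in {4} and Age in {>=1} then Outcome = Poor
if NBhypo in {High} and INSS in {2, 3, 4} and Age in {>=1} then Outcome = Poor
if NBhypo in {Low} and MYCN in {normal} then Outcome = Good
if INSS in {1, 2, 3, 4s} and MYCN in {normal} then Outcome = Good
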