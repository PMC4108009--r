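## Gestational-age strata used throughout: early <28, moderate 28-32,
## late 33-36 completed weeks; preterm = <37 weeks.
GA_LEVELS <- c("early", "moderate", "late")

DISABILITY_LEVELS <- c("none", "mild", "moderate", "severe")

## Age periods over which post-discharge utilization accrues.  The single
## discharge-to-age-2 state is followed by annual states; the final accrual
## row is age 9 (the year running from the 9th to the 10th birthday).
AGE_PERIODS <- c("discharge_to_2", as.character(2:9))
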