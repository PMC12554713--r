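# Signal-positivity thresholds. These are the conventional criteria used in
# spontaneous-report disproportionality screening; every value can be
# overridden per run.
min_cases: 3        # minimum a (drug & event case count) before any call
ror_lo_gt: 1        # ROR 95% CI lower bound must exceed this
prr_ge: 2           # PRR threshold (combined with chi2_ge)
chi2_ge: 4          # Yates chi-square threshold accompanying the PRR
ic025_gt: 0         # IC 2.5th-percentile lower credibility bound
ebgm05_gt: 2        # EBGM posterior 5th percentile
alpha: 0.05         # familywise level used with Bonferroni-adjusted p
bonferroni_m: auto  # "auto" = number of tested hypotheses in the run
rule: any           # "any": positive if any method fires; "all": all four
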