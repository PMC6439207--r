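# Tolerance of +/- 1 in the last printed digit, absorbing the source
# tables' own rounding of their F_bioa inputs.
tol_printed <- function(decimals) 10^-decimals + 1e-9

# The high-pollution biochar scenario used throughout the biochar tests.
biochar_scenario <- function() extreme_biochar_scenario()
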