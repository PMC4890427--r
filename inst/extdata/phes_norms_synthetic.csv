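subtest,mean,sd,higher_is_worse
nct_a_seconds,38.2,12.6,TRUE
nct_b_seconds,63.2,31.2,TRUE
serial_dotting_seconds,43.3,8.1,TRUE
digit_symbol_raw,44.9,9.3,FALSE
line_tracing_raw,113.8,17.9,TRUE
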