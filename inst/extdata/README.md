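# External data

This directory ships no data. Condition parameter tables consumed by
`read_parameter_table()` / `reproduce_published_analysis()` can be placed
here; the expected layout is one row per genotype-by-day condition with
columns `genotype`, `day` and the 25 canonical parameter names (see
`parameter_names()`).

In particular, `published_parameters.csv` — a published supplementary
parameter table in that layout — is looked up here by the reproduction
checks. It is not redistributable with this package and must be supplied by
the user.
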