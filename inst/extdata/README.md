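Place the study's supplementary NEXUS character matrix here as
`study-matrix.nex` (235 OTUs x 141 characters, missing `?`, gap `-`) and
reinstall the package to enable the reproduction-scale acceptance tests.
The file is not redistributed with this package.
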