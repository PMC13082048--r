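# Reference structure coordinates

Place deposited coordinate files here, named by lower-case PDB id with a
`.cif` or `.pdb` extension (e.g. `6rh3.cif`, `6asx.cif`, `6rip.cif`,
`6ri9.cif`), *before* installing the package. The published-structure
swivel-angle comparison in the test suite and in `scripts/acceptance.R`
runs only when these files are present; they are not redistributed with
the package.

Expected chain labels are the canonical `A/B = alpha, C = beta,
D = beta-prime, E = omega`; structures with other labels can be analysed
through the `query_chain_map` / `reference_chain_map` arguments of
`compute_swivel()`.
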