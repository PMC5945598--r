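# Deposited coordinate files

The acceptance checks that re-measure quantities on deposited models look
for the released coordinate files here (or under
`getOption("actifil.accession_dir")`), named in lower case:

    1j6z.pdb (or .cif)   TMR-modified G-actin monomer
    5jlf.pdb (or .cif)   bare F-actin filament (cryo-EM)
    5yu8.pdb (or .cif)   cofilin-decorated actin filament (cryo-EM)

These files are not redistributed with the package; download them from the
Protein Data Bank and place them in this directory (or set the option) to
enable the deposited-model checks. All other functionality and tests are
download-free.
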