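# Synthetic SR-protein position weight matrices

These matrices (`SRSF1`, `SRSF2`, `SRSF5`, `SRSF6`) are SYNTHETIC
stand-ins constructed for demonstration and testing of the ESE scanning
machinery. They are modeled loosely on the consensus binding preferences
of the corresponding SR splicing factors (the SRSF2 matrix is built around
a CAGCAG-type core so that disruption of a CAGCAGA word by a C>T change
is detected), but the weights and thresholds are NOT experimentally
derived. For real analyses, supply matrices from an experimental source
(e.g. the ESEfinder SELEX-derived set) in the same TSV format:

    # threshold: <score cutoff>
    pos<TAB>A<TAB>C<TAB>G<TAB>T
    1 ... one row per motif position ...

A window passes when the sum of per-position weights of its bases reaches
the threshold.
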