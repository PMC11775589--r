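# Synthetic stand-in assay design: 20-nt primer-binding sites flanking a
# 56-nt analysis region with uniform base composition. Coordinates are
# 0-based half-open. Watermarks: 5' PBS AA -> TT, 3' PBS TT -> AA.
template: GCAACTGGTACGTCAGATCGCGGTGCGCTGTTCTATTCCCTTATGATGGATCTGACGGAAACACGATCAGACAGCAGATCTTGCAGCATGCACGTC
pbs5: [0, 20]
pbs3: [76, 96]
analysis: [20, 76]
watermark5: {start: 2, from: AA, to: TT}
watermark3: {start: 80, from: TT, to: AA}
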