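# Adverse events of interest, each defined by MedDRA Preferred Terms.
# The five urate-related PTs screened individually in antihypertensive
# pharmacovigilance analyses.
events:
  - label: hyperuricaemia
    pts: [Hyperuricaemia]
  - label: gout
    pts: [Gout]
  - label: gouty arthritis
    pts: [Gouty arthritis]
  - label: gouty tophus
    pts: [Gouty tophus]
  - label: urate nephropathy
    pts: [Urate nephropathy]
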