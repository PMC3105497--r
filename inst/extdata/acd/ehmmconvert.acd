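application: ehmmconvert [
  documentation: "Convert between profile HMM file formats"
  groups: "HMM"
]

section: input [
  information: "Input section"
  type: "page"
]

  infile: hmmfile [
    parameter: "Y"
    information: "HMM file to convert"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  outfile: newhmmfile [
    parameter: "Y"
    knowntype: "hmm"
    relations: "EDAM: 1000009 ! HMMER hidden Markov model"
  ]

endsection: output
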