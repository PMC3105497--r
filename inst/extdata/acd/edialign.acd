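# ACD descriptor for edialign (synthetic reconstruction, slightly shortened)
application: edialign [
  documentation: "Local multiple alignment of sequences"
  groups: "Alignment:Multiple"
  relations: "EDAM: 2000003 ! Multiple sequence alignment"
]

section: input [
  information: "Input section"
  type: "page"
]

  seqset: sequences [
    parameter: "Y"
    type: "gapany"
    aligned: "N"
    help: "File containing a sequence alignment"
    relations: "EDAM: 1000003 ! Sequence record"
  ]

endsection: input

section: additional [
  information: "Additional section"
  type: "page"
]

  maxfraglen: maxfraglen [
    additional: "Y"
    information: "Maximum fragment length"
    default: "40"
  ]

endsection: additional

section: output [
  information: "Output section"
  type: "page"
]

  outfile: outfile [
    parameter: "Y"
    knowntype: "edialign output"
  ]

  seqoutall: seqoutall [
    parameter: "Y"
    extension: "fasta"
    relations: "EDAM: 1000003 ! Sequence record"
  ]

endsection: output
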