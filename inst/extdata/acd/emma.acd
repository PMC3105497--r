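application: emma [
  documentation: "Global multiple alignment of sequences (ClustalW wrapper)"
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
    relations: "EDAM: 1000003 ! Sequence record"
  ]

endsection: input

section: output [
  information: "Output section"
  type: "page"
]

  seqoutset: seqoutset [
    parameter: "Y"
    extension: "aln"
    relations: "EDAM: 1000003 ! Sequence record"
  ]

  outfile: dendoutfile [
    parameter: "Y"
    knowntype: "dendrogram"
  ]

endsection: output
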