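format-version: 1.2
date: 01:03:2010 12:00
saved-by: flowsynth
default-namespace: mini_edam
remark: Miniature EDAM-style ontology (synthetic reconstruction) covering the data and operation terms used by the bundled HMMER-subset ACD fixtures.

[Term]
id: EDAM:1000001
name: Data

[Term]
id: EDAM:1000002
name: Identifier
is_a: EDAM:1000001 ! Data

[Term]
id: EDAM:1000003
name: Sequence record
is_a: EDAM:1000001 ! Data

[Term]
id: EDAM:1000004
name: Protein sequence record
is_a: EDAM:1000003 ! Sequence record

[Term]
id: EDAM:1000005
name: DNA sequence record
is_a: EDAM:1000003 ! Sequence record

[Term]
id: EDAM:1000006
name: Sequence report
is_a: EDAM:1000001 ! Data

[Term]
id: EDAM:1000007
name: Sequence signature
is_a: EDAM:1000001 ! Data

[Term]
id: EDAM:1000008
name: Sequence-profile alignment
is_a: EDAM:1000001 ! Data

[Term]
id: EDAM:1000009
name: HMMER hidden Markov model
is_a: EDAM:1000008 ! Sequence-profile alignment

[Term]
id: EDAM:1000010
name: HMMER hidden Markov model identifier
is_a: EDAM:1000002 ! Identifier

[Term]
id: EDAM:1000011
name: Sequence mass
is_a: EDAM:1000001 ! Data
is_obsolete: true

[Term]
id: EDAM:2000001
name: Operation

[Term]
id: EDAM:2000002
name: Sequence alignment
is_a: EDAM:2000001 ! Operation

[Term]
id: EDAM:2000003
name: Multiple sequence alignment
is_a: EDAM:2000002 ! Sequence alignment

[Term]
id: EDAM:2000004
name: Sequence visualisation
is_a: EDAM:2000001 ! Operation
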