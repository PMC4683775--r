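format-version: 1.2
ontology: mini-phenotype

[Term]
id: MP:0000001
name: Phenotypic abnormality

[Term]
id: MP:0001626
name: Abnormality of the cardiovascular system
is_a: MP:0000001 ! Phenotypic abnormality

[Term]
id: MP:0001635
name: Congestive heart failure
is_a: MP:0001626 ! Abnormality of the cardiovascular system

[Term]
id: MP:0004421
name: Elevated systolic blood pressure
is_a: MP:0001626 ! Abnormality of the cardiovascular system
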