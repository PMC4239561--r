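format-version: 1.2
ontology: toy

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0050896
name: response to stimulus
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0044237
name: cellular metabolic process
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0006979
name: response to oxidative stress
namespace: biological_process
is_a: GO:0050896 ! response to stimulus

[Term]
id: GO:0005575
name: cellular_component
namespace: cellular_component

[Term]
id: GO:0016020
name: membrane
namespace: cellular_component
is_a: GO:0005575 ! cellular_component

[Term]
id: GO:0031090
name: organelle membrane
namespace: cellular_component
relationship: part_of GO:0016020 ! membrane

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0003824
name: catalytic activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0099999
name: retired toy term
namespace: biological_process
is_a: GO:0008150 ! biological_process
is_obsolete: true
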