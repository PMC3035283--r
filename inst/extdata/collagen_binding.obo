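format-version: 1.2

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0005488
name: binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0005515
name: protein binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0005518
name: collagen binding
namespace: molecular_function
is_a: GO:0005515 ! protein binding

[Term]
id: GO:0070052
name: collagen V binding
namespace: molecular_function
is_a: GO:0005518 ! collagen binding
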