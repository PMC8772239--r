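format-version: 1.2
default-namespace: biological_process

[Term]
id: GO:0000001
name: GO:0000001
namespace: biological_process

[Term]
id: GO:0000002
name: GO:0000002
namespace: biological_process
is_a: GO:0000001

[Term]
id: GO:0000003
name: GO:0000003
namespace: biological_process
is_a: GO:0000001

[Term]
id: GO:0000004
name: GO:0000004
namespace: biological_process
is_a: GO:0000002
is_a: GO:0000003

[Term]
id: GO:0000005
name: GO:0000005
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000006
name: GO:0000006
namespace: biological_process
is_a: GO:0000004

[Term]
id: GO:0000007
name: GO:0000007
namespace: biological_process
is_a: GO:0000004
is_a: GO:0000005

[Term]
id: GO:0000008
name: GO:0000008
namespace: biological_process
is_a: GO:0000006
is_a: GO:0000007

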