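read-1	gene-1	100	100
read-2	gene-1	100	100
read-2	gene-2	99	80
read-2	gene-3	95	80
read-3	gene-1	100	100
read-3	gene-2	100	100
read-4	gene-1	96	90
read-4	gene-2	97	90
read-4	gene-3	100	100
read-5	gene-1	95	80
read-5	gene-2	100	100
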