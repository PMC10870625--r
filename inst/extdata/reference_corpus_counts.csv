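split,annotation,sentences,DOCTOR,PATIENT,DATE,VILLE,ZIP,STR,EMAIL,PHONE
training,automatic,4948186,3883360,1853646,4948519,2544287,1305402,1165009,276208,2210577
validation,automatic,608305,479821,229925,607383,315771,162791,144654,35288,271081
test,automatic,620581,489008,232030,620028,322279,165492,147432,35322,276873
test,manual,23196,1206,510,2078,764,293,234,96,545
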