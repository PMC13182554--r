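"keyword","category"
"odorless",0
"odourless",0
"no odor",0
"no odour",0
"no smell",0
"scentless",0
"faint",1
"weak",1
"slight",1
"mild",1
"delicate",1
"moderate",2
"distinct",2
"noticeable",2
"characteristic",2
"strong",3
"intense",3
"pungent",3
"powerful",3
"penetrating",3
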