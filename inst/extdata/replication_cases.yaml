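# The seven classic discovery replication cases, with the literature
# segment of the original discovery and the number of direct-connection
# documents the protocol removes. CUIs are standard UMLS identifiers and
# are user-editable: remap them when your corpus uses a different
# vocabulary.
cases:
  - name: RD-fsh
    description: Raynaud disease - fish oil
    source_cui: C0034734
    target_cui: C0016157
    start_year: 1960
    end_year: 1985
    direct_connections: 0
  - name: Som-Arg
    description: Somatomedin C - arginine
    source_cui: C0021665
    target_cui: C0003765
    start_year: 1960
    end_year: 1989
    direct_connections: 27
  - name: Mig-Mg
    description: Migraine disorders - magnesium
    source_cui: C0149931
    target_cui: C0024467
    start_year: 1980
    end_year: 1984
    direct_connections: 0
  - name: Mg-ND
    description: Magnesium deficiency - neurologic disease
    source_cui: C0151723
    target_cui: C0027765
    start_year: 1960
    end_year: 1994
    direct_connections: 0
  - name: AD-INN
    description: Alzheimer's disease - indomethacin
    source_cui: C0002395
    target_cui: C0021246
    start_year: 1966
    end_year: 1996
    direct_connections: 6
  - name: AD-est
    description: Alzheimer's disease - estrogen
    source_cui: C0002395
    target_cui: C0014939
    start_year: 1960
    end_year: 1995
    direct_connections: 25
  - name: Sc-iPL
    description: Schizophrenia - calcium-independent phospholipase A2
    source_cui: C0036341
    target_cui: C0538273
    start_year: 1960
    end_year: 1997
    direct_connections: 1
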