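# Inclusion preset: restrict the vocabulary to the semantic areas in which
# type-restricted discovery work looks for links — chemicals & drugs, genes
# & molecular sequences, disorders, physiology and anatomy members.
# Reconstructed ST list (user-editable). The disorders contribution
# deliberately omits the finding (fndg) and sign-or-symptom (sosy) types:
# findings and symptoms are observation categories, not the disorder
# entities this restriction targets.
# chemicals & drugs
aapp
antb
bacs
bodm
chem
chvf
chvs
clnd
elii
enzy
hops
horm
imft
inch
irda
nnon
orch
phsu
rcpt
vita
# genes & molecular sequences
amas
crbs
gngm
mosq
nusq
# disorders (entity types only)
acab
anab
cgab
comd
dsyn
emod
inpo
mobd
neop
patf
# physiology
celf
clna
genf
menp
moft
orgf
orga
ortf
phsf
# anatomy members
anst
blor
bpoc
bsoj
bdsu
bdsy
celc
cell
emst
ffas
tisu
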