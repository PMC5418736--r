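interaction_type	direction
inhibitor	Anti
antagonist	Anti
blocker	Anti
antibody	Anti
antisense	Anti
antisense oligonucleotide	Anti
suppressor	Anti
negative modulator	Anti
inverse agonist	Anti
partial antagonist	Anti
inhibitory allosteric modulator	Anti
channel blocker	Anti
gating inhibitor	Anti
competitive	Anti
cleavage	Anti
siRNA	Anti
vaccine	Anti
antagonist,allosteric modulator	Anti
agonist	Pro
partial agonist	Pro
activator	Pro
inducer	Pro
positive modulator	Pro
positive allosteric modulator	Pro
stimulator	Pro
cofactor	Pro
chaperone	Pro
agonist,allosteric modulator	Pro
binder	Neither
ligand	Neither
modulator	Neither
allosteric modulator	Neither
substrate	Neither
product of	Neither
cross-reactivity	Neither
multitarget	Neither
potentiator	Neither
adduct	Neither
other/unknown	Neither
n/a	Neither
na	Neither
affinity reagent	Neither
transporter	Neither
carrier	Neither
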