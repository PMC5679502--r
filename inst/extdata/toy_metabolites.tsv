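id	name	compartment	carbon_count
glc_e	glucose (external)	external	6
xyl_e	xylose (external)	external	5
pi_e	phosphate (external)	external	0
pstor	stored phosphate (polyphosphate pool)	external	0
h_e	protons (external)	external	0
co2_e	carbon dioxide (external)	external	1
cit_e	citric acid (external, dissociated)	external	6
oxa_e	oxalic acid (external, dissociated)	external	2
glcn_e	gluconic acid (external, dissociated)	external	6
ace_e	acetic acid (external, dissociated)	external	2
mal_e	malic acid (external, dissociated)	external	4
suc_e	succinic acid (external, dissociated)	external	4
lac_e	lactic acid (external, dissociated)	external	3
c1	carbon unit	cytosol	1
p	phosphate (internal)	cytosol	0
hp	protons from acid dissociation	cytosol	0
oxa_c	oxalate (cytosolic)	cytosol	2
cit_u	citric acid (undissociated)	cytosol	6
oxa_u	oxalic acid (undissociated)	cytosol	2
glcn_u	gluconic acid (undissociated)	cytosol	6
ace_u	acetic acid (undissociated)	cytosol	2
mal_u	malic acid (undissociated)	cytosol	4
suc_u	succinic acid (undissociated)	cytosol	4
lac_u	lactic acid (undissociated)	cytosol	3
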