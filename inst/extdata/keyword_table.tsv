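keyword	category
styrene	aromatic degradation
phenylacetate	aromatic degradation
phenylpropionic	aromatic degradation
monooxygenase	aromatic degradation
dioxygenase	aromatic degradation
mercur	heavy-metal resistance
tellurite	heavy-metal resistance
chromate	heavy-metal resistance
arsen	heavy-metal resistance
copper	heavy-metal resistance
czc	heavy-metal resistance
efflux	efflux
rnd	efflux
transposase	mobile element
integrase	mobile element
insertion sequence	mobile element
resolvase	mobile element
conjugal	conjugation/T4SS
type iv secretion	conjugation/T4SS
t4ss	conjugation/T4SS
trb	conjugation/T4SS
relaxase	conjugation/T4SS
coupling protein	conjugation/T4SS
pilus	conjugation/T4SS
replication initiat	replication/partitioning
partition	replication/partitioning
para	replication/partitioning
parb	replication/partitioning
repa	replication/partitioning
trfa	replication/partitioning
chaperone	stress response
heat shock	stress response
universal stress	stress response
toxin	stress response
regulator	regulation
transcriptional	regulation
sigma	regulation
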