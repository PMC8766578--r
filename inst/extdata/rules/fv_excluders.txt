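# Whole-token excluders for the fruit & vegetable classifier: juices (and
# juice-like or soda-flavour contexts such as "cherry coke") do not count
# as fresh produce.
juice
juices
nectar
smoothie
soda
cola
coke
pop
lemonade
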