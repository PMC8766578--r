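# Fast-food chain names, one per line, pre-normalized (lowercase, no
# punctuation). An entry is fast food when its normalized brand contains
# one of these as a substring.
mcdonalds
burger king
wendys
taco bell
kfc
kentucky fried chicken
subway
pizza hut
dominos
little caesars
papa johns
chick fil a
chickfila
popeyes
arbys
sonic drive in
jack in the box
dairy queen
carls jr
hardees
whataburger
five guys
in n out
panda express
chipotle
dunkin donuts
jimmy johns
wingstop
white castle
del taco
church s chicken
churchs chicken
long john silvers
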