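# Fresh fruit & vegetable terms (MyPlate-style, juices excluded via
# fv_excluders.txt). Matched as substrings of normalized brand+description.
# This list is a synthetic, editable approximation of a fruit/vegetable
# vocabulary; it is configuration, not code.
apple
banana
orange
grape
strawberry
strawberries
blueberry
blueberries
raspberry
raspberries
blackberry
blackberries
melon
watermelon
cantaloupe
honeydew
peach
pear
plum
apricot
nectarine
cherry
cherries
pineapple
mango
papaya
kiwi
avocado
grapefruit
tangerine
clementine
pomegranate
fig
date fruit
broccoli
spinach
kale
lettuce
romaine
arugula
cabbage
carrot
celery
cucumber
zucchini
squash
pumpkin
tomato
pepper bell
bell pepper
onion
garlic
mushroom
cauliflower
asparagus
green bean
green beans
pea
peas
corn on the cob
sweet corn
beet
beets
radish
turnip
sweet potato
yam
eggplant
okra
brussels sprout
brussels sprouts
chard
collard greens
leek
artichoke
salad greens
mixed greens
fruit salad
vegetable medley
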