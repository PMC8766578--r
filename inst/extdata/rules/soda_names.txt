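# Sugary soda brand names, pre-normalized. An entry is soda when its
# normalized brand contains one of these AND its description contains no
# excluder token (diet/lite/light/zero).
coca cola
cocacola
coke
pepsi
sprite
fanta
mountain dew
mtn dew
dr pepper
7up
7 up
root beer
barqs
sierra mist
sunkist soda
crush soda
orange crush
mello yello
cherry cola
cream soda
ginger ale
squirt soda
big red soda
faygo
jolt cola
rc cola
royal crown cola
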