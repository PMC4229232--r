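muscle,vol_cm3,l_o_g_cm,l_mt_g_cm,elongated_attachment
psoas,250,10.4,24,0
iliacus,170,10.0,18,0
glmed_a,160,5.4,15,0
glmed_m,160,5.9,16,0
glmed_p,130,6.5,15,0
glmax_a,320,14.2,22,1
tfl,60,9.5,35,1
semimem,250,8.0,49,0
recfem,270,8.4,53,0
vasmed,430,8.9,31,0
vaslat,550,8.4,34,0
vasint,270,8.7,32,0
gasmed,260,4.5,55,0
gaslat,150,5.1,55,0
soleus,450,4.4,40,1
tibant,140,6.8,33,0
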