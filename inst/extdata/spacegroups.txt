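# Internal space-group operator table, xyz-triplet notation.
# Covers the Sohncke groups met in B-DNA duplex / nucleosome crystal forms.
# Centred settings list the centring translations explicitly, so each block
# is the full list of symmetry-equivalent positions.
# Block header: [Hermann-Mauguin] aliases: alias1 alias2 ...

[P 1] aliases: P1
x,y,z

[P 1 21 1] aliases: P21 P121
x,y,z
-x,y+1/2,-z

[C 1 2 1] aliases: C121 C2
x,y,z
-x,y,-z
x+1/2,y+1/2,z
-x+1/2,y+1/2,-z

[P 21 21 21] aliases: P212121
x,y,z
x+1/2,-y+1/2,-z
-x,y+1/2,-z+1/2
-x+1/2,-y,z+1/2

[I 2 2 2] aliases: I222
x,y,z
-x,-y,z
-x,y,-z
x,-y,-z
x+1/2,y+1/2,z+1/2
-x+1/2,-y+1/2,z+1/2
-x+1/2,y+1/2,-z+1/2
x+1/2,-y+1/2,-z+1/2

[R 3] aliases: R3 H3
x,y,z
-y,x-y,z
-x+y,-x,z
x+2/3,y+1/3,z+1/3
-y+2/3,x-y+1/3,z+1/3
-x+y+2/3,-x+1/3,z+1/3
x+1/3,y+2/3,z+2/3
-y+1/3,x-y+2/3,z+2/3
-x+y+1/3,-x+2/3,z+2/3

[P 31] aliases: P31
x,y,z
-y,x-y,z+1/3
-x+y,-x,z+2/3

[P 32] aliases: P32
x,y,z
-y,x-y,z+2/3
-x+y,-x,z+1/3

[P 31 2 1] aliases: P3121
x,y,z
-y,x-y,z+1/3
-x+y,-x,z+2/3
y,x,-z
x-y,-y,-z+2/3
-x,-x+y,-z+1/3

[P 32 2 1] aliases: P3221
x,y,z
-y,x-y,z+2/3
-x+y,-x,z+1/3
y,x,-z
x-y,-y,-z+1/3
-x,-x+y,-z+2/3

[P 41] aliases: P41
x,y,z
-x,-y,z+1/2
-y,x,z+1/4
y,-x,z+3/4

[P 43] aliases: P43
x,y,z
-x,-y,z+1/2
-y,x,z+3/4
y,-x,z+1/4

[P 41 2 2] aliases: P4122
x,y,z
-x,-y,z+1/2
-y,x,z+1/4
y,-x,z+3/4
-x,y,-z
x,-y,-z+1/2
y,x,-z+3/4
-y,-x,-z+1/4

[P 43 2 2] aliases: P4322
x,y,z
-x,-y,z+1/2
-y,x,z+3/4
y,-x,z+1/4
-x,y,-z
x,-y,-z+1/2
y,x,-z+1/4
-y,-x,-z+3/4

[P 61] aliases: P61
x,y,z
x-y,x,z+1/6
-y,x-y,z+1/3
-x,-y,z+1/2
-x+y,-x,z+2/3
y,-x+y,z+5/6

[P 61 2 2] aliases: P6122
x,y,z
-y,x-y,z+1/3
-x+y,-x,z+2/3
-x,-y,z+1/2
y,-x+y,z+5/6
x-y,x,z+1/6
y,x,-z+1/3
x-y,-y,-z
-x,-x+y,-z+2/3
-y,-x,-z+5/6
-x+y,y,-z+1/2
x,x-y,-z+1/6
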