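e.g
i.e
etc
vs
cf
ca
approx
dr
mr
mrs
ms
prof
sr
jr
st
no
fig
figs
al
vol
pp
ed
eds
dept
univ
inc
ltd
co
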