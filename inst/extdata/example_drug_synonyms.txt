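synonym	generic
duloxetine	duloxetine
duloxetine hydrochloride	duloxetine
cymbalta	duloxetine
drizalma	duloxetine
irenka	duloxetine
yentreve	duloxetine
venlafaxine	venlafaxine
venlafaxine hydrochloride	venlafaxine
effexor	venlafaxine
effexor xr	venlafaxine
venlafaxine er	venlafaxine
trevilor	venlafaxine
vandral	venlafaxine
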