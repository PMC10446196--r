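jonathancook13@example.org
tyler_walker@example.org
brian.lane@gmail.com
jwebb086@example.org
debra_holmes@aol.com
cheryldavis13@gmail.com
hbrown658@aol.com
anthony.bishop@yahoo.com
kenneth_taylor@yahoo.com
barbarashaw61@yahoo.com
thomas_wood@yahoo.com
stephanieparker47@example.org
melissa.walker@example.org
aford626@aol.com
gcook815@yahoo.com
ashleymorgan80@yahoo.com
anna.evans@gmail.com
richardbailey96@aol.com
amy.wilson@example.org
deborahturner38@aol.com
roger.stone@aol.com
carl.green@aol.com
joyce.reed@yahoo.com
douglas_green@outlook.com
tyler.cook@aol.com
andrea.cook@outlook.com
jennifer.stone@gmail.com
sean.bailey@yahoo.com
dorothyward81@gmail.com
maria_page@example.org
sbrown704@outlook.com
joan_fox@outlook.com
rcook754@yahoo.com
hwebb256@yahoo.com
matthewford64@gmail.com
pamelahayes78@gmail.com
katherine_shaw@example.org
kyleholmes64@gmail.com
benjamin_hayes@yahoo.com
arthur_cook@aol.com
gregoryford76@outlook.com
samanthastone40@yahoo.com
sophiawood18@outlook.com
zturner322@aol.com
barbaradavis73@outlook.com
mward028@outlook.com
dmason428@gmail.com
victoriawhite38@yahoo.com
ryanrichards68@gmail.com
angela_fox@example.org
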