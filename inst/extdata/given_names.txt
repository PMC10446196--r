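james
john
robert
michael
william
david
richard
joseph
thomas
charles
daniel
matthew
anthony
mark
donald
steven
paul
andrew
joshua
kenneth
kevin
brian
george
timothy
ronald
jason
edward
jeffrey
ryan
jacob
nicholas
eric
jonathan
stephen
justin
scott
brandon
benjamin
samuel
gregory
alexander
patrick
jack
tyler
henry
douglas
peter
adam
nathan
zachary
walter
kyle
harold
carl
jordan
gerald
keith
roger
arthur
sean
christian
albert
mary
patricia
jennifer
linda
elizabeth
barbara
susan
jessica
sarah
karen
lisa
nancy
betty
margaret
sandra
ashley
kimberly
emily
donna
michelle
carol
amanda
dorothy
melissa
deborah
stephanie
rebecca
sharon
laura
cynthia
kathleen
amy
angela
shirley
anna
brenda
pamela
emma
nicole
helen
samantha
katherine
christine
debra
rachel
carolyn
janet
catherine
maria
heather
diane
ruth
julie
olivia
joyce
virginia
victoria
kelly
lauren
christina
joan
evelyn
judith
megan
andrea
cheryl
hannah
jacqueline
martha
gloria
teresa
sara
janice
julia
grace
judy
sophia
denise
abigail
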