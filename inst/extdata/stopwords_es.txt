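a
al
algo
algunas
algunos
ante
antes
como
con
contra
cual
cuando
de
del
desde
donde
durante
e
el
ella
ellas
ellos
en
entre
era
erais
eran
eras
eres
es
esa
esas
ese
eso
esos
esta
estaba
estado
estamos
estar
estas
este
esto
estos
estoy
fue
fueron
fui
fuimos
ha
habia
había
han
has
hasta
hay
la
las
le
les
lo
los
mas
más
me
mi
mis
mucho
muchos
muy
nada
ni
no
nos
nosotras
nosotros
nuestra
nuestras
nuestro
nuestros
o
os
otra
otras
otro
otros
para
pero
poco
por
porque
que
quien
quienes
qué
se
sea
sean
segun
según
ser
si
sido
sin
sobre
sois
somos
son
soy
su
sus
te
tenemos
tener
tengo
ti
tiene
tienen
todo
todos
tu
tus
tú
un
una
unas
uno
unos
usted
ustedes
vosotras
vosotros
y
ya
yo
él
ésta
éste
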