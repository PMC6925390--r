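word,polarity,subjectivity
good,0.7,0.6
great,0.8,0.75
awesome,1.0,1.0
amazing,0.9,0.9
excellent,1.0,1.0
happy,0.8,1.0
love,0.5,0.6
loved,0.7,0.8
like,0.3,0.4
fun,0.5,0.4
nice,0.6,1.0
best,1.0,0.3
better,0.5,0.5
wonderful,1.0,1.0
fantastic,0.9,0.9
excited,0.4,0.8
glad,0.5,1.0
beautiful,0.85,1.0
perfect,1.0,1.0
cool,0.35,0.65
sweet,0.35,0.65
chill,0.3,0.5
relaxed,0.4,0.6
rested,0.5,0.6
energized,0.6,0.7
fresh,0.3,0.4
win,0.8,0.6
winning,0.7,0.7
success,0.7,0.6
proud,0.6,0.8
laugh,0.5,0.6
smile,0.55,0.65
enjoy,0.5,0.5
enjoyed,0.6,0.6
yay,0.8,0.9
woo,0.6,0.9
lit,0.5,0.8
blessed,0.7,0.9
grateful,0.6,0.8
thanks,0.4,0.4
thankful,0.6,0.8
delicious,0.8,0.9
tasty,0.6,0.8
friendly,0.5,0.6
funny,0.5,0.7
hilarious,0.7,0.9
interesting,0.5,0.5
motivated,0.5,0.7
productive,0.5,0.5
calm,0.3,0.4
bad,-0.7,0.67
terrible,-1.0,1.0
awful,-1.0,1.0
horrible,-1.0,1.0
worst,-1.0,0.3
sad,-0.5,1.0
unhappy,-0.6,0.9
angry,-0.5,0.9
mad,-0.6,0.9
hate,-0.8,0.9
hated,-0.9,0.95
tired,-0.4,0.7
exhausted,-0.8,0.9
sleepy,-0.3,0.6
drained,-0.6,0.8
drowsy,-0.4,0.6
groggy,-0.5,0.7
weary,-0.5,0.7
fatigued,-0.6,0.8
zombie,-0.5,0.8
dead,-0.6,0.75
dying,-0.7,0.85
stressed,-0.6,0.85
stress,-0.5,0.7
anxious,-0.5,0.85
worried,-0.4,0.8
scared,-0.6,0.9
afraid,-0.6,0.9
fail,-0.7,0.6
failed,-0.8,0.7
failing,-0.7,0.7
lose,-0.4,0.5
losing,-0.5,0.6
lost,-0.4,0.5
sick,-0.7,0.85
ill,-0.6,0.8
pain,-0.6,0.7
hurt,-0.6,0.8
cry,-0.5,0.8
crying,-0.6,0.9
miserable,-0.9,1.0
depressed,-0.8,0.95
lonely,-0.6,0.9
bored,-0.5,0.8
boring,-0.6,0.9
annoyed,-0.5,0.8
annoying,-0.6,0.9
frustrated,-0.6,0.85
ugh,-0.6,0.9
meh,-0.2,0.6
late,-0.3,0.6
broke,-0.4,0.6
broken,-0.4,0.6
wrong,-0.5,0.5
difficult,-0.5,0.7
hard,-0.3,0.4
struggle,-0.5,0.7
struggling,-0.6,0.8
overwhelmed,-0.6,0.85
nervous,-0.4,0.8
panic,-0.7,0.9
dread,-0.6,0.8
gloomy,-0.5,0.8
grumpy,-0.5,0.8
cranky,-0.5,0.8
irritated,-0.5,0.8
restless,-0.4,0.7
insomnia,-0.5,0.6
nightmare,-0.8,0.9
okay,0.2,0.5
fine,0.2,0.4
alright,0.15,0.45
whatever,-0.1,0.6
busy,-0.1,0.4
quiet,0.1,0.4
new,0.1,0.4
old,-0.1,0.3
long,-0.05,0.4
short,0.0,0.4
neutral,0.0,0.0
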